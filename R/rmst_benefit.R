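# Restricted mean survival time under endpoint-specific truncation rules,
# the simplified clinical-benefit grading, and the PD-L1 predictive-value
# statistic.

#' Choose the RMST truncation time
#'
#' Defaults are 24 months for OS and 12 months for PFS; when the minimum
#' over arms of the largest observed time is shorter than the default, that
#' minimum is used instead.
#'
#' @param observations Two-arm observations.
#' @param endpoint `"OS"` or `"PFS"`.
#' @return Truncation time tau in months.
#' @export
choose_truncation <- function(observations, endpoint = "OS") {
  obs <- as.data.frame(observations)
  if (!all(.arms %in% obs$arm)) stop("both arms must be non-empty", call. = FALSE)
  default <- if (endpoint == "OS") 24 else 12
  min_max <- min(vapply(.arms, function(a) max(obs$time[obs$arm == a]),
                        numeric(1)))
  min(default, min_max)
}

# Area under the KM curve on [0, tau] with the standard nonparametric
# (Greenwood-type) variance of the restricted mean: for each event time
# t_i <= tau, the residual area A_i = int_{t_i}^{tau} S(u) du contributes
# A_i^2 d_i / (n_i (n_i - d_i)).
.rmst_one_arm <- function(time, event, tau) {
  if (tau > max(time))
    stop("tau exceeds the arm's largest observed time", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- sf$n.event > 0 & sf$time <= tau
  tt <- sf$time[keep]; dd <- sf$n.event[keep]
  nn <- sf$n.risk[keep]; ss <- sf$surv[keep]
  knots <- c(0, tt, tau)
  vals <- c(1, ss)
  areas <- diff(knots) * vals            # area of each flat stretch
  rmst <- sum(areas)
  if (length(tt)) {
    resid <- rev(cumsum(rev(areas[-1]))) # A_i: area to the right of each t_i
    terms <- ifelse(nn > dd, dd / (nn * (nn - dd)), 0)
    v <- sum(resid^2 * terms)
  } else v <- 0
  c(rmst = rmst, se = sqrt(v))
}

#' Restricted mean survival time difference
#'
#' Per-arm RMST is the area under the KM curve up to `tau`; the difference
#' (experimental minus control) carries a normal-approximation confidence
#' interval and p-value, and represents the absolute survival gain or loss
#' over the truncation window.
#'
#' @param observations Two-arm observations.
#' @param tau Truncation time (months), at most the largest observed time in
#'   each arm.
#' @param conf_level Confidence level.
#' @return Object of class `rmst_result`: `tau`, per-arm `rmst` and `se`,
#'   `difference`, `ci_low`, `ci_high`, `p_value`.
#' @export
rmst_difference <- function(observations, tau, conf_level = 0.95) {
  obs <- as.data.frame(observations)
  if (!all(.arms %in% obs$arm)) stop("both arms must be non-empty", call. = FALSE)
  res <- lapply(.arms, function(a)
    .rmst_one_arm(obs$time[obs$arm == a], obs$event[obs$arm == a], tau))
  names(res) <- .arms
  diff <- res$experimental["rmst"] - res$control["rmst"]
  se <- sqrt(res$experimental["se"]^2 + res$control["se"]^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(tau = tau,
                 rmst_experimental = unname(res$experimental["rmst"]),
                 se_experimental = unname(res$experimental["se"]),
                 rmst_control = unname(res$control["rmst"]),
                 se_control = unname(res$control["se"]),
                 difference = unname(diff),
                 ci_low = unname(diff - z * se),
                 ci_high = unname(diff + z * se),
                 p_value = unname(2 * stats::pnorm(-abs(diff / se)))),
            class = "rmst_result")
}

#' @export
print.rmst_result <- function(x, ...) {
  cat(sprintf("RMST (tau = %g months): %.2f vs %.2f; difference %.2f (%.2f-%.2f), p = %.4g\n",
              x$tau, x$rmst_experimental, x$rmst_control, x$difference,
              x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Scan truncation times for the first significant RMST difference
#'
#' Evaluates [rmst_difference()] over a grid of truncation times and returns
#' the earliest tau whose confidence interval excludes 0, used to locate the
#' follow-up time at which a (possibly delayed) treatment effect first
#' becomes detectable.
#'
#' @param observations Two-arm observations.
#' @param taus Grid of truncation times (months) within follow-up.
#' @param conf_level Confidence level.
#' @return List with `first_significant` (a tau, or `NA` for "none") and the
#'   full `table` of scan results.
#' @export
rmst_scan <- function(observations, taus, conf_level = 0.95) {
  if (!length(taus)) stop("empty truncation grid", call. = FALSE)
  taus <- sort(taus)
  rows <- lapply(taus, function(tau) {
    r <- rmst_difference(observations, tau, conf_level)
    data.frame(tau = tau, difference = r$difference, ci_low = r$ci_low,
               ci_high = r$ci_high, p_value = r$p_value)
  })
  tab <- do.call(rbind, rows)
  sig <- tab$tau[tab$ci_low > 0 | tab$ci_high < 0]
  list(first_significant = if (length(sig)) sig[1] else NA_real_, table = tab)
}

#' Simplified clinical-benefit grade
#'
#' Applies the simplified benefit scale for overall survival: with a control
#' median of at most 12 months, an experimental median better by >= 2 months
#' is meaningful; with a control median over 12 and at most 24 months, a
#' gain of >= 3 months is meaningful; with the median not reached, an
#' absolute 10-percentage-point increase in 2-year OS is meaningful. In all
#' cases the upper 95% confidence limit of the HR must be below 1.
#' Meaningful outcomes are labeled "grade 3 (meaningful)" (the printed scale
#' does not distinguish grades 3 and 4). A control median above 24 months
#' with medians reached falls outside the stated bands and returns an
#' explicit "rule undefined" outcome. The scale covers OS; PFS is refused
#' unless `allow_pfs_override = TRUE`.
#'
#' @param control_median,experimental_median Medians in months; `NA` or
#'   `Inf` mean not reached.
#' @param hr_ci_upper Upper 95% confidence limit of the hazard ratio.
#' @param two_year_os Optional length-2 numeric `c(experimental, control)`
#'   2-year survival probabilities; required when the control median is not
#'   reached.
#' @param endpoint Endpoint the medians refer to.
#' @param allow_pfs_override Set `TRUE` to apply the OS scale to PFS anyway.
#' @return Object of class `benefit_grade`: `meaningful`, `grade_label`,
#'   `rule_applied`, and the echoed inputs.
#' @export
grade_benefit <- function(control_median, experimental_median, hr_ci_upper,
                          two_year_os = NULL, endpoint = "OS",
                          allow_pfs_override = FALSE) {
  if (endpoint != "OS" && !allow_pfs_override)
    stop("the simplified benefit scale is stated for OS only; ",
         "set allow_pfs_override = TRUE to apply it regardless", call. = FALSE)
  not_reached <- function(x) is.na(x) || !is.finite(x)
  inputs <- list(control_median = control_median,
                 experimental_median = experimental_median,
                 hr_ci_upper = hr_ci_upper, two_year_os = two_year_os)
  finish <- function(meaningful, rule) {
    structure(list(meaningful = meaningful,
                   grade_label = if (isTRUE(meaningful)) "grade 3 (meaningful)"
                                 else if (is.na(meaningful)) "rule undefined"
                                 else "not meaningful",
                   rule_applied = rule, inputs = inputs),
              class = "benefit_grade")
  }
  if (not_reached(control_median)) {
    if (is.null(two_year_os) || length(two_year_os) != 2)
      stop("two_year_os = c(experimental, control) required when the control median is not reached",
           call. = FALSE)
    gain <- two_year_os[1] - two_year_os[2]
    return(finish(gain >= 0.10 && hr_ci_upper < 1, "os_rate_2yr"))
  }
  gain <- (if (not_reached(experimental_median)) Inf else experimental_median) -
    control_median
  if (control_median <= 12)
    return(finish(gain >= 2 && hr_ci_upper < 1, "median_le12"))
  if (control_median <= 24)
    return(finish(gain >= 3 && hr_ci_upper < 1, "median_12to24"))
  finish(NA, "undefined")
}

#' @export
print.benefit_grade <- function(x, ...) {
  cat(sprintf("Clinical benefit: %s (rule: %s)\n", x$grade_label, x$rule_applied))
  invisible(x)
}

#' Predictive value of PD-L1 expression
#'
#' Natural log of the ratio of the hazard ratio in the PD-L1 < 1% population
#' to that in the PD-L1 >= 1% population. Positive values mean the drug
#' effect is stronger in the PD-L1-expressing population, i.e. PD-L1
#' expression predicts benefit.
#'
#' @param hr_low Hazard ratio in the PD-L1 < 1% population.
#' @param hr_high Hazard ratio in the PD-L1 >= 1% population.
#' @return List with `pv`, `hr_low`, `hr_high`.
#' @export
predictive_value <- function(hr_low, hr_high) {
  if (hr_low <= 0 || hr_high <= 0)
    stop("hazard ratios must be positive", call. = FALSE)
  list(pv = log(hr_low / hr_high), hr_low = hr_low, hr_high = hr_high)
}
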