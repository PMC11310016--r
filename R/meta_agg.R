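# Two-stage random-effects meta-analysis of aggregate hazard ratios
# (optionally combined with per-trial HRs derived from reconstructed IPD),
# publication-bias diagnostics, and the IPD-representativeness comparison.
# DerSimonian-Laird pooling is delegated to metafor; the Egger regression and
# between-stratum Q tests are computed here.

.effects_to_yi <- function(effects) {
  ef <- validate_effects(effects)
  yi <- log(ef$hr)
  sei <- (log(ef$ci_high) - log(ef$ci_low)) / (2 * 1.96)
  if (any(sei <= 0))
    stop("effects: degenerate CI (upper <= lower)", call. = FALSE)
  data.frame(trial_id = ef$trial_id, yi = yi, sei = sei)
}

.pool_dl <- function(yi, sei) {
  fit <- metafor::rma(yi = yi, sei = sei, method = "DL")
  w <- metafor::weights.rma.uni(fit) / 100
  list(log_hr = as.numeric(fit$b), se = fit$se,
       hr = exp(as.numeric(fit$b)),
       ci_low = exp(as.numeric(fit$ci.lb)), ci_high = exp(as.numeric(fit$ci.ub)),
       p_value = fit$pval, tau2 = fit$tau2, Q = fit$QE, p_q = fit$QEp,
       weights = w, k = fit$k)
}

.pool_subset <- function(yi, sei) {
  if (length(yi) >= 2) return(.pool_dl(yi, sei))
  list(log_hr = yi, se = sei, hr = exp(yi),
       ci_low = exp(yi - 1.96 * sei), ci_high = exp(yi + 1.96 * sei),
       p_value = 2 * stats::pnorm(-abs(yi / sei)), tau2 = 0,
       Q = NA_real_, p_q = NA_real_, weights = 1, k = 1L)
}

#' Random-effects pooling of hazard ratios
#'
#' DerSimonian-Laird random-effects model on the log-HR scale; standard
#' errors are derived from the reported 95% confidence limits as
#' `(log U - log L) / (2 * 1.96)`. With `stratify_by`, each stratum is
#' pooled separately and a between-stratum Q test (inverse-variance weights
#' on the stratum means, chi-square with strata - 1 df) gives the
#' subgroup-difference p-value.
#'
#' @param effects Data frame of aggregate effects (`trial_id, endpoint, hr,
#'   ci_low, ci_high`, optional `weight_n`).
#' @param stratify_by Optional vector (same length as rows of `effects`) or
#'   name of a column in `effects` defining strata.
#' @return Object of class `meta_result`: pooled `hr`, `ci_low`, `ci_high`,
#'   `p_value`, `tau2`, per-study `weights` (summing to 1), `Q`, `p_q`, and
#'   when stratified a `strata` table plus `p_subgroup_difference`.
#' @export
pool_random_effects <- function(effects, stratify_by = NULL) {
  d <- .effects_to_yi(effects)
  if (nrow(d) < 2) stop("at least 2 effects required", call. = FALSE)
  overall <- .pool_dl(d$yi, d$sei)
  strata <- NULL; p_diff <- NULL
  if (!is.null(stratify_by)) {
    g <- if (length(stratify_by) == 1 && is.character(stratify_by) &&
             stratify_by %in% names(effects)) effects[[stratify_by]]
         else stratify_by
    stopifnot(length(g) == nrow(d))
    per <- lapply(split(seq_len(nrow(d)), g), function(idx)
      .pool_subset(d$yi[idx], d$sei[idx]))
    strata <- data.frame(stratum = names(per),
                         k = vapply(per, `[[`, numeric(1), "k"),
                         hr = vapply(per, `[[`, numeric(1), "hr"),
                         ci_low = vapply(per, `[[`, numeric(1), "ci_low"),
                         ci_high = vapply(per, `[[`, numeric(1), "ci_high"),
                         tau2 = vapply(per, `[[`, numeric(1), "tau2"))
    b <- vapply(per, `[[`, numeric(1), "log_hr")
    s <- vapply(per, `[[`, numeric(1), "se")
    w <- 1 / s^2
    mu <- sum(w * b) / sum(w)
    Qb <- sum(w * (b - mu)^2)
    p_diff <- stats::pchisq(Qb, length(b) - 1, lower.tail = FALSE)
  }
  structure(c(overall, list(strata = strata,
                            p_subgroup_difference = p_diff)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Random-effects pool (%d studies): HR %.3f (%.3f-%.3f), tau^2 = %.4f, Q p = %.3g\n",
              x$k, x$hr, x$ci_low, x$ci_high, x$tau2, x$p_q))
  if (!is.null(x$p_subgroup_difference))
    cat(sprintf("  p for subgroup difference = %.4g\n", x$p_subgroup_difference))
  invisible(x)
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' Regression of the standardized effect (log HR / SE) on precision (1 / SE);
#' the intercept estimates small-study asymmetry, with a two-tailed t-test.
#' Funnel coordinates (effect vs standard error) are returned for plotting.
#'
#' @param effects Data frame of aggregate effects (>= 3 rows).
#' @return Object of class `bias_report`: `intercept`, `ci_low`, `ci_high`,
#'   `p_value`, and `funnel` (data frame `log_hr`, `se`).
#' @export
eggers_test <- function(effects) {
  d <- .effects_to_yi(effects)
  if (nrow(d) < 3) stop("Egger's test requires at least 3 effects", call. = FALSE)
  z <- d$yi / d$sei
  prec <- 1 / d$sei
  if (stats::var(prec) < 1e-12) {
    # identical precisions: the regression is degenerate and the funnel is
    # perfectly symmetric by construction
    return(structure(list(intercept = 0, ci_low = 0, ci_high = 0,
                          p_value = 1, degenerate = TRUE,
                          funnel = data.frame(trial_id = d$trial_id,
                                              log_hr = d$yi, se = d$sei)),
                     class = "bias_report"))
  }
  fit <- stats::lm(z ~ prec)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)["(Intercept)", ]
  structure(list(intercept = unname(sm["(Intercept)", "Estimate"]),
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 p_value = unname(sm["(Intercept)", "Pr(>|t|)"]),
                 funnel = data.frame(trial_id = d$trial_id, log_hr = d$yi,
                                     se = d$sei)),
            class = "bias_report")
}

#' Compare IPD-available trials with the total evidence base
#'
#' Pools the hazard ratios of trials with curve-level data and of all trials
#' (IPD plus aggregate) separately, and tests the difference between the two
#' pooled estimates with a between-group Q statistic (chi-square, 1 df). A
#' non-significant difference supports treating the IPD subset as
#' representative of the total evidence.
#'
#' @param effects Data frame of aggregate effects for all trials.
#' @param ipd_flags Logical vector marking the IPD-available rows.
#' @return List with the two pooled `meta_result`s, `p_difference`, and the
#'   `comparable` verdict (`p_difference > 0.05`).
#' @export
compare_ipd_vs_total <- function(effects, ipd_flags) {
  stopifnot(length(ipd_flags) == nrow(effects))
  if (!any(ipd_flags)) stop("IPD subset is empty", call. = FALSE)
  if (!any(!ipd_flags)) {
    pooled <- pool_random_effects(effects)
    return(list(ipd = pooled, total = pooled, p_difference = 1,
                comparable = TRUE))
  }
  d <- .effects_to_yi(effects)
  ipd <- .pool_subset(d$yi[ipd_flags], d$sei[ipd_flags])
  total <- .pool_subset(d$yi, d$sei)
  Qb <- (ipd$log_hr - total$log_hr)^2 / (ipd$se^2 + total$se^2)
  p <- stats::pchisq(Qb, 1, lower.tail = FALSE)
  list(ipd = ipd, total = total, p_difference = p, comparable = p > 0.05)
}
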