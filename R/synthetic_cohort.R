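# Synthetic multi-trial generator: piecewise-exponential event times with a
# latent PD-L1 subgroup mixture, trial-level gamma frailty, optional delayed
# treatment effect, uniform accrual with administrative censoring, and a
# renderer that degrades exact IPD into published-figure-style curve
# coordinates and number-at-risk tables.

#' Piecewise-constant hazard specification
#'
#' Hazards are constant within segments delimited by `bounds` (months,
#' strictly increasing from 0; the last segment is open-ended). `rates` is a
#' named list of per-segment hazard vectors (events per patient-month), keyed
#' either per arm (`"control"`, `"experimental"`, applied to both PD-L1
#' subgroups) or per arm-by-subgroup cell
#' (e.g. `"experimental.pdl1_lt1"`).
#'
#' @param bounds Numeric vector of segment start times, beginning at 0.
#' @param rates Named list of non-negative numeric vectors, each of length
#'   `length(bounds)`.
#' @return An object of class `hazard_spec`.
#' @export
hazard_spec <- function(bounds, rates) {
  bounds <- as.numeric(bounds)
  if (bounds[1] != 0 || any(diff(bounds) <= 0))
    stop("bounds must be strictly increasing from 0", call. = FALSE)
  for (nm in names(rates)) {
    r <- rates[[nm]]
    if (length(r) != length(bounds) || any(r < 0) || any(!is.finite(r)))
      stop("rates[['", nm, "']] must be non-negative, finite, one per segment",
           call. = FALSE)
  }
  structure(list(bounds = bounds, rates = lapply(rates, as.numeric)),
            class = "hazard_spec")
}

# Exponential hazards from per-cell median survival / hazard-ratio shorthand.
#' Exponential hazard specification from control median and hazard ratio
#'
#' Single-segment (constant-hazard) shorthand: the control arm has hazard
#' `log(2) / median_control` and the experimental arm that hazard times `hr`,
#' identically in both PD-L1 subgroups unless subgroup-specific ratios are
#' given.
#'
#' @param median_control Control-arm median survival in months.
#' @param hr Experimental-vs-control hazard ratio.
#' @param hr_lt1,hr_ge1 Optional subgroup-specific hazard ratios overriding
#'   `hr`.
#' @return A `hazard_spec`.
#' @export
exponential_hazard <- function(median_control, hr = 1, hr_lt1 = NULL, hr_ge1 = NULL) {
  lam <- log(2) / median_control
  if (is.null(hr_lt1) && is.null(hr_ge1))
    return(hazard_spec(0, list(control = lam, experimental = lam * hr)))
  if (is.null(hr_lt1)) hr_lt1 <- hr
  if (is.null(hr_ge1)) hr_ge1 <- hr
  hazard_spec(0, list(control.pdl1_lt1 = lam, control.pdl1_ge1 = lam,
                      experimental.pdl1_lt1 = lam * hr_lt1,
                      experimental.pdl1_ge1 = lam * hr_ge1))
}

.hazard_rates <- function(hs, arm, subgroup) {
  key <- paste(arm, subgroup, sep = ".")
  if (!is.null(hs$rates[[key]])) return(hs$rates[[key]])
  if (!is.null(hs$rates[[arm]])) return(hs$rates[[arm]])
  stop("hazard_spec has no rates for ", key, call. = FALSE)
}

#' Trial simulation specification
#'
#' Bundles the design parameters of one synthetic randomized trial: arm size,
#' latent PD-L1 < 1% share, the piecewise hazard model, trial-level frailty
#' variance, uniform accrual window, administrative censoring horizon,
#' exponential dropout, and an optional delayed treatment effect (before
#' `delayed_effect_month` the experimental arm runs at control hazards).
#'
#' @param n_per_arm Patients per arm.
#' @param hazard A `hazard_spec`.
#' @param subgroup_fraction Probability a patient is PD-L1 < 1%.
#' @param frailty_variance Variance of the mean-1 gamma trial frailty.
#' @param accrual_months Uniform accrual window (months).
#' @param admin_censor_month Administrative censoring, months after trial
#'   start (must exceed 0; may be `Inf` only if other censoring exists).
#' @param dropout_rate Per-month exponential dropout hazard.
#' @param delayed_effect_month Months before which the experimental arm
#'   hazard equals control.
#' @param trial_id Identifier used in generated observations.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param cancer_type,regimen,drug_class,control_type,assay_clone,scoring_method
#'   Registry metadata attached to the generated trial record.
#' @return An object of class `trial_sim_spec`.
#' @export
trial_sim_spec <- function(n_per_arm, hazard, subgroup_fraction = 0.4,
                           frailty_variance = 0, accrual_months = 12,
                           admin_censor_month = 36, dropout_rate = 0,
                           delayed_effect_month = 0, trial_id = "SIM-1",
                           endpoint = "OS", cancer_type = "NSCLC",
                           regimen = "combination", drug_class = "anti-PD-1",
                           control_type = "chemo", assay_clone = "22C3",
                           scoring_method = "TPS") {
  stopifnot(n_per_arm >= 1, subgroup_fraction >= 0, subgroup_fraction <= 1,
            frailty_variance >= 0, accrual_months >= 0,
            admin_censor_month > 0, dropout_rate >= 0,
            delayed_effect_month >= 0)
  stopifnot(inherits(hazard, "hazard_spec"))
  structure(list(n_per_arm = as.integer(n_per_arm), hazard = hazard,
                 subgroup_fraction = subgroup_fraction,
                 frailty_variance = frailty_variance,
                 accrual_months = accrual_months,
                 admin_censor_month = admin_censor_month,
                 dropout_rate = dropout_rate,
                 delayed_effect_month = delayed_effect_month,
                 trial_id = trial_id, endpoint = endpoint,
                 cancer_type = cancer_type, regimen = regimen,
                 drug_class = drug_class, control_type = control_type,
                 assay_clone = assay_clone, scoring_method = scoring_method),
            class = "trial_sim_spec")
}

# Inverse-CDF draw from a piecewise-exponential: solve cumulative hazard
# Lambda(t) = E for E ~ Exp(1). Returns Inf when total hazard is exhausted.
.piecewise_draw <- function(E, bounds, rates) {
  k <- length(bounds)
  widths <- c(diff(bounds), Inf)
  acc <- 0
  for (i in seq_len(k)) {
    seg_h <- rates[i] * widths[i]   # Inf * 0 cannot occur (rates finite)
    if (is.nan(seg_h)) seg_h <- 0
    if (acc + seg_h >= E) {
      if (rates[i] == 0) return(bounds[i])  # unreachable: seg_h would be 0 < E - acc
      return(bounds[i] + (E - acc) / rates[i])
    }
    acc <- acc + seg_h
  }
  Inf
}

# Refine (bounds, rates) so that the experimental arm runs at control rates
# before the delayed-effect onset.
.apply_delay <- function(bounds, exp_rates, ctrl_rates, delay) {
  if (delay <= 0) return(list(bounds = bounds, rates = exp_rates))
  grid <- sort(unique(c(bounds, delay)))
  idx <- findInterval(grid, bounds)
  r <- ifelse(grid < delay, ctrl_rates[idx], exp_rates[idx])
  list(bounds = grid, rates = r)
}

#' Simulate one randomized trial
#'
#' Event times are drawn from the piecewise-exponential model by inversion of
#' the cumulative hazard; censoring is the minimum of administrative
#' censoring under uniform accrual (`admin_censor_month - entry`) and
#' exponential dropout. Subgroup labels are Bernoulli draws with probability
#' `subgroup_fraction`. Exactly `2 * n_per_arm` observations are returned,
#' reproducibly for a fixed seed.
#'
#' @param spec A `trial_sim_spec`.
#' @param seed Integer seed.
#' @param frailty Multiplicative hazard factor applied to both arms (used by
#'   [simulate_program()]; default 1).
#' @return Data frame of observations with a `true_frailty` attribute.
#' @export
simulate_trial <- function(spec, seed = NULL, frailty = 1) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  any_rate <- any(unlist(spec$hazard$rates) > 0)
  if (!any_rate && spec$dropout_rate == 0 && !is.finite(spec$admin_censor_month))
    stop("no finite observation possible: all hazards zero, no dropout, infinite admin censoring",
         call. = FALSE)
  n <- spec$n_per_arm
  out <- vector("list", 2L)
  for (a in seq_along(.arms)) {
    arm <- .arms[a]
    sub <- ifelse(stats::runif(n) < spec$subgroup_fraction, "pdl1_lt1", "pdl1_ge1")
    entry <- if (spec$accrual_months > 0) stats::runif(n, 0, spec$accrual_months) else rep(0, n)
    admin <- pmax(spec$admin_censor_month - entry, 0)
    drop_t <- if (spec$dropout_rate > 0) stats::rexp(n, spec$dropout_rate) else rep(Inf, n)
    cens <- pmin(admin, drop_t)
    E <- stats::rexp(n)
    tt <- numeric(n)
    for (i in seq_len(n)) {
      rates <- .hazard_rates(spec$hazard, arm, sub[i]) * frailty
      pw <- if (arm == "experimental")
        .apply_delay(spec$hazard$bounds, rates,
                     .hazard_rates(spec$hazard, "control", sub[i]) * frailty,
                     spec$delayed_effect_month)
      else list(bounds = spec$hazard$bounds, rates = rates)
      tt[i] <- .piecewise_draw(E[i], pw$bounds, pw$rates)
    }
    obs_t <- pmin(tt, cens)
    ev <- as.integer(tt <= cens)
    if (any(!is.finite(obs_t)))
      stop("non-finite observation time generated; check censoring settings",
           call. = FALSE)
    out[[a]] <- data.frame(trial_id = spec$trial_id, arm = arm,
                           endpoint = spec$endpoint, subgroup = sub,
                           time = obs_t, event = ev,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "true_frailty") <- frailty
  res
}

#' Simulate a multi-trial program
#'
#' Draws one mean-1 gamma frailty per trial (variance `frailty_variance` from
#' each spec) and applies it to both arms' hazards, then simulates every
#' trial. Registry counts are tallied from the generated observations.
#'
#' @param specs List of `trial_sim_spec` objects.
#' @param seed Integer seed.
#' @return List with elements `registry` (a `trial_registry`), `ipd`
#'   (observations for all trials), and `frailties` (named numeric).
#' @export
simulate_program <- function(specs, seed = NULL) {
  if (length(specs) == 0) stop("at least one trial spec is required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  frail <- vapply(specs, function(sp) {
    th <- sp$frailty_variance
    if (th <= 0) 1 else stats::rgamma(1, shape = 1 / th, rate = 1 / th)
  }, numeric(1))
  seeds <- sample.int(.Machine$integer.max, length(specs))
  obs <- vector("list", length(specs))
  reg <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    obs[[i]] <- simulate_trial(sp, seed = seeds[i], frailty = frail[i])
    n_low <- sum(obs[[i]]$subgroup == "pdl1_lt1")
    n_tot <- nrow(obs[[i]])
    reg[[i]] <- data.frame(trial_id = sp$trial_id, cancer_type = sp$cancer_type,
                           regimen = sp$regimen, drug_class = sp$drug_class,
                           control_type = sp$control_type,
                           assay_clone = sp$assay_clone,
                           scoring_method = sp$scoring_method,
                           n_low_pdl1 = n_low, n_total = n_tot,
                           pct_printed = round(100 * n_low / n_tot, 1),
                           ipd_available = TRUE, stringsAsFactors = FALSE)
  }
  registry <- do.call(rbind, reg)
  class(registry) <- c("trial_registry", "data.frame")
  names(frail) <- vapply(specs, `[[`, character(1), "trial_id")
  list(registry = registry, ipd = do.call(rbind, obs), frailties = frail)
}

# Exact KM step function (event times, survival after each drop) for one cell.
.km_steps <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
             n_event = sf$n.event)
}

.km_eval <- function(steps, t) {
  # right-continuous step function, S(0) = 1
  ev <- steps[steps$n_event > 0, , drop = FALSE]
  vapply(t, function(x) {
    below <- ev$time <= x
    if (!any(below)) 1 else ev$surv[max(which(below))]
  }, numeric(1))
}

#' Render observations into a digitized curve and risk table
#'
#' Emulates what a reader obtains from a published figure: the exact KM step
#' function sampled at every event time plus a regular coordinate grid,
#' optionally perturbed by truncated Gaussian jitter and re-projected to a
#' monotone non-increasing sequence in [0, 1]; and exact counts still at risk
#' at multiples of `risk_interval`.
#'
#' @param observations Observations for one (trial, arm, endpoint, subgroup)
#'   cell.
#' @param risk_interval Spacing of number-at-risk times (months, > 0).
#' @param coordinate_step Spacing of the regular coordinate grid (months).
#' @param jitter_sd Standard deviation of digitization noise on the survival
#'   scale (0 = exact).
#' @param subgroup_label Label recorded on the outputs (defaults to the
#'   observations' subgroup if unique, else `"overall"`).
#' @return List with elements `curve` (`digitized_curve`) and `risk`
#'   (`risk_table`).
#' @export
render_km <- function(observations, risk_interval = 3, coordinate_step = 1,
                      jitter_sd = 0, subgroup_label = NULL) {
  obs <- as.data.frame(observations)
  if (nrow(obs) == 0) stop("no observations to render", call. = FALSE)
  if (risk_interval <= 0) stop("risk_interval must be > 0", call. = FALSE)
  stopifnot(length(unique(obs$trial_id)) == 1, length(unique(obs$arm)) == 1)
  if (is.null(subgroup_label)) {
    sgs <- unique(obs$subgroup)
    subgroup_label <- if (length(sgs) == 1) sgs else "overall"
  }
  steps <- .km_steps(obs$time, obs$event)
  tmax <- max(obs$time)
  grid <- sort(unique(c(0, steps$time[steps$n_event > 0],
                        seq(0, tmax, by = coordinate_step), tmax)))
  surv <- .km_eval(steps, grid)
  if (jitter_sd > 0) {
    noise <- stats::rnorm(length(surv), 0, jitter_sd)
    noise[1] <- 0                       # anchor (0, 1)
    surv <- pmin(pmax(surv + noise, 0), 1)
    # isotonic (non-increasing) projection, then re-clamp
    surv <- -stats::isoreg(grid, -surv)$yf
    surv <- pmin(pmax(surv, 0), 1)
    surv[1] <- 1
  }
  curve <- digitized_curve(obs$trial_id[1], obs$arm[1], obs$endpoint[1],
                           subgroup_label, grid, surv)
  rt_times <- seq(0, tmax, by = risk_interval)
  n_risk <- vapply(rt_times, function(t) sum(obs$time >= t), integer(1))
  risk <- risk_table(obs$trial_id[1], obs$arm[1], obs$endpoint[1],
                     subgroup_label, rt_times, n_risk)
  list(curve = curve, risk = risk)
}
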