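# Orchestration of the full chain: simulate -> render -> reconstruct ->
# subtract -> validate -> pool -> tvhr -> rmst -> grade -> meta. Each stage
# reads and writes the CSV/JSON schemas of the data model inside one output
# directory and records a manifest (inputs, parameters, derived seed,
# package version, config hash), so reruns with the same config and seed are
# reproducible stage by stage.

.known_config_keys <- c("seed", "out_dir", "endpoint", "simulate", "render",
                        "subtract", "pool", "tvhr", "rmst", "grade", "meta")

.load_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  config
}

# Per-stage substream: the global seed plus a stage-name-keyed offset, so a
# single stage can be rerun without perturbing the others.
.stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 7919L) %% 2000000000L
}

.config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

.manifest <- function(out_dir, stage, inputs, outputs, params, seed, config) {
  m <- list(stage = stage, inputs = inputs, outputs = outputs,
            parameters = params, seed = seed,
            config_hash = .config_hash(config),
            package_version = as.character(utils::packageVersion("icimeta")))
  jsonlite::write_json(m, file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(m)
}

.sim_specs_from_config <- function(cfg) {
  sc <- cfg$simulate
  n_trials <- sc$n_trials %||% 6
  hr_lt1 <- sc$hr_lt1 %||% 0.8
  hr_ge1 <- sc$hr_ge1 %||% 0.7
  lapply(seq_len(n_trials), function(i)
    trial_sim_spec(
      n_per_arm = sc$n_per_arm %||% 150,
      hazard = exponential_hazard(sc$median_control %||% 12,
                                  hr_lt1 = hr_lt1, hr_ge1 = hr_ge1),
      subgroup_fraction = sc$subgroup_fraction %||% 0.4,
      frailty_variance = sc$frailty_variance %||% 0.1,
      accrual_months = sc$accrual_months %||% 12,
      admin_censor_month = sc$admin_censor_month %||% 36,
      dropout_rate = sc$dropout_rate %||% 0.005,
      delayed_effect_month = sc$delayed_effect_month %||% 0,
      trial_id = sprintf("SIM-%02d", i),
      endpoint = cfg$endpoint %||% "OS"))
}

.stage_simulate <- function(cfg, out_dir) {
  seed <- .stage_seed(cfg$seed %||% 1, "simulate")
  prog <- simulate_program(.sim_specs_from_config(cfg), seed = seed)
  reg_path <- file.path(out_dir, "registry.csv")
  utils::write.csv(as.data.frame(prog$registry), reg_path, row.names = FALSE)
  ipd_path <- file.path(out_dir, "ipd_true.csv")
  write_ipd(prog$ipd, ipd_path)
  .manifest(out_dir, "simulate", character(0), c(reg_path, ipd_path),
            cfg$simulate, seed, cfg)
}

.stage_render <- function(cfg, out_dir) {
  seed <- .stage_seed(cfg$seed %||% 1, "render")
  set.seed(seed)
  rc <- cfg$render
  ipd <- read_ipd(file.path(out_dir, "ipd_true.csv"))
  curves <- list(); risks <- list()
  for (tid in unique(ipd$trial_id)) for (a in .arms) {
    cell <- ipd[ipd$trial_id == tid & ipd$arm == a, ]
    # published-figure emulation: overall and PD-L1 >= 1% curves reported,
    # the PD-L1 < 1% subgroup left unreported
    for (sg in c("overall", "pdl1_ge1")) {
      sub <- if (sg == "overall") cell else cell[cell$subgroup == sg, ]
      if (!nrow(sub)) next
      r <- render_km(sub, risk_interval = rc$risk_interval %||% 3,
                     coordinate_step = rc$coordinate_step %||% 1,
                     jitter_sd = rc$jitter_sd %||% 0, subgroup_label = sg)
      key <- paste(tid, a, sg)
      curves[[key]] <- r$curve; risks[[key]] <- r$risk
    }
  }
  write_curves(curves, file.path(out_dir, "curves.csv"))
  write_risk_tables(risks, file.path(out_dir, "risk.csv"))
  .manifest(out_dir, "render", file.path(out_dir, "ipd_true.csv"),
            file.path(out_dir, c("curves.csv", "risk.csv")), rc, seed, cfg)
}

.stage_reconstruct <- function(cfg, out_dir) {
  curves <- read_curves(file.path(out_dir, "curves.csv"))
  risks <- read_risk_tables(file.path(out_dir, "risk.csv"))
  obs <- list()
  for (key in names(curves)) {
    if (is.null(risks[[key]])) stop("no risk table for cell ", key, call. = FALSE)
    obs[[key]] <- reconstruct_ipd(curves[[key]], risks[[key]])$observations
  }
  out <- do.call(rbind, obs)
  write_ipd(out, file.path(out_dir, "ipd_reconstructed.csv"))
  .manifest(out_dir, "reconstruct", file.path(out_dir, c("curves.csv", "risk.csv")),
            file.path(out_dir, "ipd_reconstructed.csv"), list(),
            .stage_seed(cfg$seed %||% 1, "reconstruct"), cfg)
}

.stage_subtract <- function(cfg, out_dir) {
  rec <- read_ipd(file.path(out_dir, "ipd_reconstructed.csv"))
  spec <- match_spec(cfg$subtract$event_mismatch_penalty)
  out <- list()
  for (tid in unique(rec$trial_id)) {
    overall <- rec[rec$trial_id == tid & rec$subgroup == "overall", ]
    known <- rec[rec$trial_id == tid & rec$subgroup == "pdl1_ge1", ]
    out[[tid]] <- subtract_subgroup(overall, known, spec)
  }
  lt1 <- do.call(rbind, out)
  write_ipd(lt1, file.path(out_dir, "ipd_lt1.csv"))
  .manifest(out_dir, "subtract", file.path(out_dir, "ipd_reconstructed.csv"),
            file.path(out_dir, "ipd_lt1.csv"), cfg$subtract,
            .stage_seed(cfg$seed %||% 1, "subtract"), cfg)
}

.stage_validate <- function(cfg, out_dir) {
  lt1 <- read_ipd(file.path(out_dir, "ipd_lt1.csv"))
  truth_path <- file.path(out_dir, "ipd_true.csv")
  if (!file.exists(truth_path))
    stop("validate requires ipd_true.csv (simulated ground truth)", call. = FALSE)
  truth <- read_ipd(truth_path)
  truth <- truth[truth$subgroup == "pdl1_lt1", ]
  refs <- do.call(rbind, lapply(split(truth, truth$trial_id), function(d) {
    s <- .arm_summaries(d)
    data.frame(trial_id = d$trial_id[1], hr = s$hr,
               median_experimental = s$median_experimental,
               median_control = s$median_control)
  }))
  qc <- validate_reconstruction(split(lt1, lt1$trial_id), refs)
  jsonlite::write_json(list(pearson = as.list(qc$pearson),
                            correlation_omitted = qc$correlation_omitted,
                            table = qc$table),
                       file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .manifest(out_dir, "validate",
            file.path(out_dir, c("ipd_lt1.csv", "ipd_true.csv")),
            file.path(out_dir, "qc_report.json"), list(),
            .stage_seed(cfg$seed %||% 1, "validate"), cfg)
}

.analysis_ipd <- function(out_dir) {
  p <- file.path(out_dir, "ipd_lt1.csv")
  if (!file.exists(p)) stop("missing input: ", p, call. = FALSE)
  read_ipd(p)
}

.stage_pool <- function(cfg, out_dir) {
  ipd <- .analysis_ipd(out_dir)
  registry <- load_registry(file.path(out_dir, "registry.csv"))
  covars <- cfg$pool$covariates %||% c("cancer_type", "drug_class", "control_type")
  lr <- logrank_test(ipd)
  marg <- cox_marginal(ipd, registry, covars)
  frail <- if (length(unique(ipd$trial_id)) >= 2)
    cox_shared_frailty(ipd, registry, covars) else NULL
  per_trial <- do.call(rbind, lapply(split(ipd, ipd$trial_id), function(d) {
    f <- tryCatch(cox_marginal(d, cluster = NULL), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(trial_id = d$trial_id[1], endpoint = d$endpoint[1], hr = f$hr,
               ci_low = f$ci_low, ci_high = f$ci_high, weight_n = f$n)
  }))
  utils::write.csv(per_trial, file.path(out_dir, "per_trial_effects.csv"),
                   row.names = FALSE)
  res <- list(logrank = lr,
              marginal_cox = unclass(marg),
              shared_frailty_cox = if (!is.null(frail)) unclass(frail),
              seed = cfg$seed %||% 1)
  jsonlite::write_json(res, file.path(out_dir, "pooled_results.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .manifest(out_dir, "pool",
            file.path(out_dir, c("ipd_lt1.csv", "registry.csv")),
            file.path(out_dir, c("pooled_results.json", "per_trial_effects.csv")),
            list(covariates = covars), .stage_seed(cfg$seed %||% 1, "pool"), cfg)
}

.stage_tvhr <- function(cfg, out_dir) {
  ipd <- .analysis_ipd(out_dir)
  registry <- load_registry(file.path(out_dir, "registry.csv"))
  seed <- .stage_seed(cfg$seed %||% 1, "tvhr")
  tc <- cfg$tvhr
  fit <- fit_piecewise_tvhr(ipd, registry, endpoint = cfg$endpoint %||% "OS",
                            covariates = tc$covariates,
                            mcmc = list(chains = tc$chains %||% 4,
                                        iterations = tc$iterations %||% 1000,
                                        warmup = tc$warmup %||% 500,
                                        seed = seed))
  out <- list(segments = fit$segments, average_hr = fit$average_hr,
              rhat_max = fit$rhat_max, converged = fit$converged,
              settings = fit$settings)
  jsonlite::write_json(out, file.path(out_dir, "tvhr_fit.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .manifest(out_dir, "tvhr",
            file.path(out_dir, c("ipd_lt1.csv", "registry.csv")),
            file.path(out_dir, "tvhr_fit.json"), fit$settings, seed, cfg)
}

.stage_rmst <- function(cfg, out_dir) {
  ipd <- .analysis_ipd(out_dir)
  endpoint <- cfg$endpoint %||% "OS"
  tau <- choose_truncation(ipd, endpoint)
  r <- rmst_difference(ipd, tau)
  scan <- rmst_scan(ipd, taus = seq(3, tau, by = 1))
  tab <- data.frame(tau = r$tau, rmst_experimental = r$rmst_experimental,
                    rmst_control = r$rmst_control, difference = r$difference,
                    ci_low = r$ci_low, ci_high = r$ci_high, p = r$p_value,
                    first_significant_tau = scan$first_significant)
  utils::write.csv(tab, file.path(out_dir, "rmst_results.csv"), row.names = FALSE)
  .manifest(out_dir, "rmst", file.path(out_dir, "ipd_lt1.csv"),
            file.path(out_dir, "rmst_results.csv"), list(tau = tau),
            .stage_seed(cfg$seed %||% 1, "rmst"), cfg)
}

.stage_grade <- function(cfg, out_dir) {
  ipd <- .analysis_ipd(out_dir)
  marg <- cox_marginal(ipd)
  med <- lapply(.arms, function(a) km_estimate(ipd[ipd$arm == a, ]))
  names(med) <- .arms
  two_year <- vapply(.arms, function(a)
    km_survival_at(med[[a]], 24)$surv, numeric(1))
  g <- grade_benefit(med$control$median, med$experimental$median,
                     marg$ci_high, two_year_os = rev(unname(two_year)))
  jsonlite::write_json(list(grade_label = g$grade_label,
                            meaningful = g$meaningful,
                            rule_applied = g$rule_applied,
                            inputs = g$inputs),
                       file.path(out_dir, "grades.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .manifest(out_dir, "grade", file.path(out_dir, "ipd_lt1.csv"),
            file.path(out_dir, "grades.json"), list(),
            .stage_seed(cfg$seed %||% 1, "grade"), cfg)
}

.stage_meta <- function(cfg, out_dir) {
  effects <- utils::read.csv(file.path(out_dir, "per_trial_effects.csv"),
                             stringsAsFactors = FALSE)
  extra <- cfg$meta$aggregate_effects
  ipd_flags <- rep(TRUE, nrow(effects))
  if (!is.null(extra)) {
    agg <- read_effects(extra)
    effects <- rbind(effects, agg[, names(effects)])
    ipd_flags <- c(ipd_flags, rep(FALSE, nrow(agg)))
  }
  pooled <- pool_random_effects(effects)
  bias <- if (nrow(effects) >= 3) eggers_test(effects) else NULL
  cmp <- if (any(!ipd_flags)) compare_ipd_vs_total(effects, ipd_flags) else NULL
  if (!is.null(bias))
    utils::write.csv(bias$funnel, file.path(out_dir, "funnel.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(pooled = list(hr = pooled$hr, ci_low = pooled$ci_low,
                       ci_high = pooled$ci_high, tau2 = pooled$tau2,
                       Q = pooled$Q, p_q = pooled$p_q),
         egger = if (!is.null(bias)) list(intercept = bias$intercept,
                                          p_value = bias$p_value),
         ipd_vs_total = if (!is.null(cmp)) list(p_difference = cmp$p_difference,
                                                comparable = cmp$comparable),
         seed = cfg$seed %||% 1),
    file.path(out_dir, "meta_results.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  .manifest(out_dir, "meta", file.path(out_dir, "per_trial_effects.csv"),
            file.path(out_dir, c("meta_results.json", "funnel.csv")), list(),
            .stage_seed(cfg$seed %||% 1, "meta"), cfg)
}

#' Run the analysis pipeline
#'
#' Executes one stage or the full chain on a configuration (a list, or a
#' path to a YAML/JSON file). Stage outputs land in `out_dir` with a
#' per-stage manifest recording inputs, parameters, the stage-derived seed,
#' the config hash and the package version. Rerunning with the same config
#' and seed reproduces all outputs.
#'
#' @param command One of `simulate, render, reconstruct, subtract, validate,
#'   pool, tvhr, rmst, grade, meta, all`.
#' @param config Configuration list or file path. Unknown keys fail fast.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @param seed Global seed (overrides `config$seed`); per-stage substreams
#'   are derived from it by stage name.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(command = "all", config = list(), out_dir = NULL,
                         seed = NULL) {
  stages <- c("simulate", "render", "reconstruct", "subtract", "validate",
              "pool", "tvhr", "rmst", "grade", "meta")
  command <- match.arg(command, c(stages, "all"))
  cfg <- .load_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) stop("out_dir must be given", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  todo <- if (command == "all") stages else command
  runners <- list(simulate = .stage_simulate, render = .stage_render,
                  reconstruct = .stage_reconstruct, subtract = .stage_subtract,
                  validate = .stage_validate, pool = .stage_pool,
                  tvhr = .stage_tvhr, rmst = .stage_rmst,
                  grade = .stage_grade, meta = .stage_meta)
  for (st in todo) {
    message("[icimeta] stage: ", st)
    runners[[st]](cfg, cfg$out_dir)
  }
  invisible(cfg$out_dir)
}
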