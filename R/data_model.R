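# Domain vocabularies shared across the pipeline. All times are months.

.cancer_types <- c("NSCLC", "SCLC", "ESCC", "GC", "RCC", "TNBC", "OC", "HCC",
                   "UC", "HNSCC", "MPM", "NPC", "melanoma")
.regimens <- c("mono", "combination")
.drug_classes <- c("anti-PD-1", "anti-PD-L1")
.assay_clones <- c("22C3", "28-8", "SP142", "SP263", "JS311")
.scoring_methods <- c("TPS", "IPS", "TPS&IPS", "CPS")
.arms <- c("control", "experimental")
.endpoints <- c("OS", "PFS")
.subgroups <- c("pdl1_lt1", "pdl1_ge1", "overall")

.registry_cols <- c("trial_id", "cancer_type", "regimen", "drug_class",
                    "control_type", "assay_clone", "scoring_method",
                    "n_low_pdl1", "n_total", "pct_printed", "ipd_available")
.ipd_cols <- c("trial_id", "arm", "endpoint", "subgroup", "time_months", "event")
.curve_cols <- c("trial_id", "arm", "endpoint", "subgroup", "time_months", "survival")
.risk_cols <- c("trial_id", "arm", "endpoint", "subgroup", "time_months", "n_at_risk")
.effect_cols <- c("trial_id", "endpoint", "hr", "ci_low", "ci_high", "weight_n")

.check_enum <- function(x, allowed, what) {
  bad <- which(!(x %in% allowed))
  if (length(bad))
    stop(sprintf("invalid %s in row(s) %s: %s (allowed: %s)", what,
                 paste(utils::head(bad, 5), collapse = ", "),
                 paste(unique(x[bad]), collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

.check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Load a trial registry table
#'
#' Reads the registry CSV (one row per randomized trial: cancer type, regimen
#' class, drug class, control-arm category, PD-L1 assay clone and IHC scoring
#' method, patient counts, and whether curve-level data were available) and
#' validates every row against the domain invariants. The registry bundled
#' with the package (`system.file("extdata", "table1_registry.csv",
#' package = "icimeta")`) covers 49 first-line phase 3 trials of PD-1/PD-L1
#' blockade. The printed percentage column is stored verbatim but all computed
#' percentages derive from the counts.
#'
#' @param path Path to a registry CSV with the documented header.
#' @return A `data.frame` of validated trial records (class `trial_registry`).
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .check_cols(df, .registry_cols, "registry")
  df <- df[, .registry_cols]
  if (nrow(df) == 0) {
    class(df) <- c("trial_registry", "data.frame")
    return(df)
  }
  for (col in c("n_low_pdl1", "n_total")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v != round(v) | v < 0)
    if (length(bad))
      stop(sprintf("registry: non-numeric or negative %s in row(s) %s",
                   col, paste(bad, collapse = ", ")), call. = FALSE)
    df[[col]] <- as.integer(v)
  }
  .check_enum(df$cancer_type, .cancer_types, "cancer_type")
  .check_enum(df$regimen, .regimens, "regimen")
  .check_enum(df$drug_class, .drug_classes, "drug_class")
  .check_enum(df$assay_clone, .assay_clones, "assay_clone")
  .check_enum(df$scoring_method, .scoring_methods, "scoring_method")
  dup <- duplicated(df$trial_id)
  if (any(dup))
    stop("registry: duplicate trial_id in row(s) ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  bad <- which(df$n_total <= 0)
  if (length(bad))
    stop("registry: n_total must be > 0 in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(df$n_low_pdl1 > df$n_total)
  if (length(bad))
    stop("registry: n_low_pdl1 > n_total in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  df$ipd_available <- as.logical(df$ipd_available)
  class(df) <- c("trial_registry", "data.frame")
  df
}

#' Bundled 49-trial registry
#'
#' Convenience loader for the registry shipped with the package.
#' @return A validated `trial_registry` data frame with 49 rows.
#' @export
bundled_registry <- function() {
  load_registry(system.file("extdata", "table1_registry.csv",
                            package = "icimeta", mustWork = TRUE))
}

.validate_ipd <- function(df, what = "ipd") {
  if (nrow(df) == 0) return(df)
  bad <- which(!is.finite(df$time) | df$time < 0)
  if (length(bad))
    stop(sprintf("%s: negative or non-finite time in row(s) %s", what,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  bad <- which(!(df$event %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("%s: event flag outside {0,1} in row(s) %s", what,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  .check_enum(df$arm, .arms, "arm")
  .check_enum(df$endpoint, .endpoints, "endpoint")
  .check_enum(df$subgroup, .subgroups, "subgroup")
  df
}

#' Read / write individual patient data
#'
#' IPD files carry one row per reconstructed or simulated patient:
#' `trial_id, arm, endpoint, subgroup, time_months, event`. Times are months
#' from randomization; `event` is 1 for an event, 0 for censoring. Writing
#' then reading valid data is the identity.
#'
#' @param path CSV path.
#' @return `read_ipd`: a data frame with columns `trial_id, arm, endpoint,
#'   subgroup, time, event`.
#' @export
read_ipd <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, .ipd_cols, "ipd")
  df <- df[, .ipd_cols]
  names(df)[names(df) == "time_months"] <- "time"
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  .validate_ipd(df)
}

#' @rdname read_ipd
#' @param observations Data frame of survival observations (columns
#'   `trial_id, arm, endpoint, subgroup, time, event`).
#' @export
write_ipd <- function(observations, path) {
  obs <- .validate_ipd(as.data.frame(observations))
  out <- data.frame(trial_id = obs$trial_id, arm = obs$arm,
                    endpoint = obs$endpoint, subgroup = obs$subgroup,
                    time_months = obs$time, event = obs$event)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Construct a digitized KM curve object
#'
#' A `digitized_curve` stands in for coordinates read off a published
#' Kaplan-Meier figure: an ordered set of (time, survival) points for one
#' (trial, arm, endpoint, subgroup) cell. After [preprocess_curve()] the
#' points start at (0, 1), are strictly increasing in time and non-increasing
#' in survival.
#'
#' @param trial_id,arm,endpoint,subgroup Cell labels.
#' @param time,survival Numeric vectors of equal length.
#' @return An object of class `digitized_curve`.
#' @export
digitized_curve <- function(trial_id, arm, endpoint, subgroup, time, survival) {
  stopifnot(length(time) == length(survival))
  structure(list(trial_id = trial_id, arm = arm, endpoint = endpoint,
                 subgroup = subgroup,
                 points = data.frame(time = as.numeric(time),
                                     survival = as.numeric(survival))),
            class = "digitized_curve")
}

#' Construct a number-at-risk table object
#'
#' Counts of patients still under observation at scheduled times, as printed
#' beneath a published KM plot. Times must be strictly increasing from 0,
#' counts non-increasing, and the entry at time 0 equals the arm sample size.
#'
#' @param trial_id,arm,endpoint,subgroup Cell labels.
#' @param time,n_at_risk Numeric vectors of equal length.
#' @return An object of class `risk_table`.
#' @export
risk_table <- function(trial_id, arm, endpoint, subgroup, time, n_at_risk) {
  stopifnot(length(time) == length(n_at_risk))
  time <- as.numeric(time); n_at_risk <- as.integer(n_at_risk)
  if (time[1] != 0) stop("risk table must start at time 0", call. = FALSE)
  if (any(diff(time) <= 0)) stop("risk table times must be strictly increasing",
                                 call. = FALSE)
  if (any(diff(n_at_risk) > 0)) stop("n_at_risk must be non-increasing",
                                     call. = FALSE)
  structure(list(trial_id = trial_id, arm = arm, endpoint = endpoint,
                 subgroup = subgroup,
                 entries = data.frame(time = time, n_at_risk = n_at_risk)),
            class = "risk_table")
}

.cell_key <- function(x) paste(x$trial_id, x$arm, x$endpoint, x$subgroup, sep = "|")

#' Read / write digitized curves and risk tables
#'
#' Long-format CSVs holding one or more cells; each (trial, arm, endpoint,
#' subgroup) combination becomes one `digitized_curve` / `risk_table`.
#'
#' @param path CSV path.
#' @return A named list of `digitized_curve` (resp. `risk_table`) objects.
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, .curve_cols, "curves")
  out <- lapply(split(df, paste(df$trial_id, df$arm, df$endpoint, df$subgroup,
                                sep = "|")), function(d) {
    d <- d[order(d$time_months), ]
    digitized_curve(d$trial_id[1], d$arm[1], d$endpoint[1], d$subgroup[1],
                    d$time_months, d$survival)
  })
  out
}

#' @rdname read_curves
#' @param curves List of `digitized_curve` objects.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "digitized_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cv)
    data.frame(trial_id = cv$trial_id, arm = cv$arm, endpoint = cv$endpoint,
               subgroup = cv$subgroup, time_months = cv$points$time,
               survival = cv$points$survival)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_curves
#' @export
read_risk_tables <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, .risk_cols, "risk")
  lapply(split(df, paste(df$trial_id, df$arm, df$endpoint, df$subgroup,
                         sep = "|")), function(d) {
    d <- d[order(d$time_months), ]
    risk_table(d$trial_id[1], d$arm[1], d$endpoint[1], d$subgroup[1],
               d$time_months, d$n_at_risk)
  })
}

#' @rdname read_curves
#' @param tables List of `risk_table` objects.
#' @export
write_risk_tables <- function(tables, path) {
  if (inherits(tables, "risk_table")) tables <- list(tables)
  rows <- do.call(rbind, lapply(tables, function(rt)
    data.frame(trial_id = rt$trial_id, arm = rt$arm, endpoint = rt$endpoint,
               subgroup = rt$subgroup, time_months = rt$entries$time,
               n_at_risk = rt$entries$n_at_risk)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read aggregate per-trial effects
#'
#' Aggregate effects are published hazard ratios with 95% confidence
#' intervals, used by the two-stage meta-analysis for trials without
#' curve-level data. Rows violating `0 < ci_low <= hr <= ci_high` are
#' rejected with their row index.
#'
#' @param path CSV with columns `trial_id, endpoint, hr, ci_low, ci_high,
#'   weight_n` (`weight_n` may be empty).
#' @return A data frame of validated aggregate effects.
#' @export
read_effects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, setdiff(.effect_cols, "weight_n"), "effects")
  if (is.null(df$weight_n)) df$weight_n <- NA_integer_
  validate_effects(df)
}

#' @rdname read_effects
#' @param effects Data frame of aggregate effects.
#' @export
validate_effects <- function(effects) {
  df <- as.data.frame(effects)
  for (col in c("hr", "ci_low", "ci_high")) df[[col]] <- as.numeric(df[[col]])
  bad <- which(!(df$ci_low > 0 & df$ci_low <= df$hr & df$hr <= df$ci_high))
  if (length(bad))
    stop("effects: CI must satisfy 0 < ci_low <= hr <= ci_high; row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  .check_enum(df$endpoint, .endpoints, "endpoint")
  df
}

#' Convert between months and years
#'
#' All package computations use months; these helpers are explicit and never
#' applied implicitly.
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @export
months_to_years <- function(x) x / 12

#' @rdname months_to_years
#' @export
years_to_months <- function(x) x * 12
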