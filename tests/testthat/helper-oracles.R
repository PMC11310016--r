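# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force minimum assignment cost: enumerate all ways to assign each of
# m left nodes to a distinct right node (m <= n).
brute_force_min_cost <- function(cost) {
  m <- nrow(cost); n <- ncol(cost)
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > m) { best <<- acc; return() }
    for (j in seq_len(n)) if (!used[j]) {
      used[j] <- TRUE
      rec(i + 1, used, acc + cost[i, j])
      used[j] <- FALSE
    }
  }
  rec(1, rep(FALSE, n), 0)
  best
}

# Hand log-rank statistic: observed-minus-expected over event times with the
# hypergeometric variance.
hand_logrank <- function(time, event, group) {
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Spreadsheet-style DerSimonian-Laird pooling from HRs and 95% CIs.
hand_dl_pool <- function(hr, lo, hi) {
  yi <- log(hr)
  sei <- (log(hi) - log(lo)) / (2 * 1.96)
  wi <- 1 / sei^2
  mu_fe <- sum(wi * yi) / sum(wi)
  Q <- sum(wi * (yi - mu_fe)^2)
  k <- length(yi)
  tau2 <- max(0, (Q - (k - 1)) / (sum(wi) - sum(wi^2) / sum(wi)))
  wr <- 1 / (sei^2 + tau2)
  mu <- sum(wr * yi) / sum(wr)
  list(hr = exp(mu), tau2 = tau2,
       ci_low = exp(mu - 1.96 / sqrt(sum(wr))),
       ci_high = exp(mu + 1.96 / sqrt(sum(wr))))
}

# Exact area under a right-continuous step survival curve up to tau.
step_rmst <- function(times, surv, tau) {
  # times: drop times; surv: value after each drop; S = 1 before first drop
  knots <- c(0, times[times < tau], tau)
  vals <- c(1, surv[times < tau])
  sum(diff(knots) * vals)
}

# Unadjusted two-arm Cox HR, for reference summaries.
ref_cox_hr <- function(obs) {
  f <- survival::coxph(
    survival::Surv(time, event) ~ factor(arm, levels = c("control", "experimental")),
    data = obs, ties = "efron")
  unname(exp(stats::coef(f)))
}
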