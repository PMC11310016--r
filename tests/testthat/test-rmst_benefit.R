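two_arm_df <- function(tc, ec, te, ee) {
  rbind(data.frame(trial_id = "T", arm = "control", endpoint = "OS",
                   subgroup = "overall", time = tc, event = ec),
        data.frame(trial_id = "T", arm = "experimental", endpoint = "OS",
                   subgroup = "overall", time = te, event = ee))
}

test_that("truncation follows the endpoint default and the minimum-follow-up rule", {
  long <- two_arm_df(c(10, 30), c(1, 0), c(12, 31), c(1, 0))
  expect_equal(choose_truncation(long, "OS"), 24)
  expect_equal(choose_truncation(long, "PFS"), 12)
  short <- two_arm_df(c(10, 18), c(1, 0), c(12, 30), c(1, 0))
  expect_equal(choose_truncation(short, "OS"), 18)
})

test_that("RMST equals tau with no events and exact rectangle sums on steps", {
  none <- two_arm_df(c(30, 30, 30), 0, c(30, 30, 30), 0)
  r <- rmst_difference(none, 24)
  expect_equal(r$rmst_control, 24)
  expect_equal(r$rmst_experimental, 24)
  expect_equal(r$difference, 0)

  # S = 1 on [0,6), 0.5 on [6,12): area = 6 + 3 = 9
  step <- two_arm_df(c(6, 6, 12, 12), c(1, 1, 0, 0), c(6, 6, 12, 12), c(1, 1, 0, 0))
  r2 <- rmst_difference(step, 12)
  expect_equal(r2$rmst_control, 9)
  expect_equal(r2$rmst_control, step_rmst(6, 0.5, 12))

  expect_error(rmst_difference(two_arm_df(10, 1, 30, 0), 24), "largest observed")
})

test_that("RMST on random step curves equals the rectangle-sum oracle", {
  set.seed(5)
  for (rep in 1:4) {
    tms <- sort(sample(1:20, 5))
    d <- two_arm_df(c(tms, 25, 25), c(rep(1, 5), 0, 0),
                    c(tms, 25, 25), c(rep(1, 5), 0, 0))
    km <- km_estimate(d[d$arm == "control", ])
    ev <- km$steps[km$steps$n_event > 0, ]
    r <- rmst_difference(d, 22)
    expect_equal(r$rmst_control, step_rmst(ev$time, ev$surv, 22),
                 tolerance = 1e-9)
  }
})

test_that("RMST matches the exponential closed form across hazard levels", {
  for (lam in c(0.02, 0.05, 0.1)) {
    med <- log(2) / lam
    obs <- sim_two_arm(n = 4000, hr = 1, median_control = med, seed = 1000 + med,
                       accrual = 0, admin = 200, dropout = 0)
    tau <- 24
    r <- rmst_difference(obs, tau)
    closed <- (1 - exp(-tau * lam)) / lam
    # 3 MC standard errors via the estimator's own SE
    expect_lt(abs(r$rmst_control - closed), 3 * r$se_control)
  }
  # paper-style magnitude: median 12 months, tau 24 -> 12.98 months
  expect_equal((1 - exp(-24 * log(2) / 12)) / (log(2) / 12), 12.98,
               tolerance = 0.001)
})

test_that("the truncation scan finds no effect in identical arms and a late onset in delayed effects", {
  same <- sim_two_arm(n = 400, hr = 1, seed = 3)
  scan0 <- rmst_scan(same, taus = seq(6, 24, by = 3))
  expect_true(is.na(scan0$first_significant))

  delayed <- sim_two_arm(n = 4000, hr = 0.55, seed = 4, delayed = 12,
                         accrual = 0, admin = 40, dropout = 0)
  scan1 <- rmst_scan(delayed, taus = seq(3, 30, by = 1))
  expect_false(is.na(scan1$first_significant))
  expect_gt(scan1$first_significant, 6)

  expect_error(rmst_scan(same, numeric(0)), "empty")
})

test_that("benefit grading reproduces the worked clinical examples", {
  g1 <- grade_benefit(16.3, 19.5, 0.88)
  expect_true(g1$meaningful)
  expect_equal(g1$grade_label, "grade 3 (meaningful)")
  expect_equal(g1$rule_applied, "median_12to24")

  g2 <- grade_benefit(13.6, 14.1, 1.01)
  expect_false(g2$meaningful)
  expect_equal(g2$grade_label, "not meaningful")

  # boundary-inclusive 2-month rule for low control medians
  g3 <- grade_benefit(10.0, 12.0, 0.90)
  expect_true(g3$meaningful)
  expect_equal(g3$rule_applied, "median_le12")

  # medians not reached: 10-percentage-point 2-year OS rule
  g4 <- grade_benefit(NA, NA, 0.85, two_year_os = c(0.56, 0.45))
  expect_true(g4$meaningful)
  expect_equal(g4$rule_applied, "os_rate_2yr")

  # outside the stated bands: explicit undefined outcome
  g5 <- grade_benefit(30, 34, 0.9)
  expect_true(is.na(g5$meaningful))
  expect_equal(g5$grade_label, "rule undefined")

  expect_error(grade_benefit(10, 13, 0.9, endpoint = "PFS"), "OS only")
  expect_s3_class(grade_benefit(10, 13, 0.9, endpoint = "PFS",
                                allow_pfs_override = TRUE), "benefit_grade")
})

test_that("benefit grading is monotone in the experimental median", {
  meaningful_at <- function(exp_med) grade_benefit(14, exp_med, 0.9)$meaningful
  res <- vapply(seq(14, 22, by = 0.5), meaningful_at, logical(1))
  expect_true(all(diff(res) >= 0))   # never flips back to not meaningful
})

test_that("predictive value is the log HR ratio with antisymmetry", {
  expect_equal(predictive_value(0.8, 0.8)$pv, 0)
  expect_equal(predictive_value(0.9, 0.6)$pv, log(1.5), tolerance = 1e-12)
  expect_equal(predictive_value(0.6, 0.9)$pv, -predictive_value(0.9, 0.6)$pv)
  expect_error(predictive_value(-1, 0.5), "positive")
})
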