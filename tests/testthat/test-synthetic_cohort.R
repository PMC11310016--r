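test_that("zero hazards with administrative censoring only censor everyone at the horizon", {
  sp <- trial_sim_spec(10, hazard_spec(0, list(control = 0, experimental = 0)),
                       accrual_months = 0, admin_censor_month = 24,
                       dropout_rate = 0)
  obs <- simulate_trial(sp, seed = 1)
  expect_equal(nrow(obs), 20)
  expect_true(all(obs$time == 24))
  expect_true(all(obs$event == 0))
})

test_that("simulation with no finite observation possible is refused", {
  sp <- trial_sim_spec(5, hazard_spec(0, list(control = 0, experimental = 0)),
                       accrual_months = 0, admin_censor_month = Inf,
                       dropout_rate = 0)
  expect_error(simulate_trial(sp, seed = 1), "no finite observation")
})

test_that("exponential event times reproduce the closed-form median", {
  # lambda = ln 2 / 10 => median 10 months
  obs <- sim_two_arm(n = 5000, hr = 1, median_control = 10, seed = 42,
                     accrual = 0, admin = 300, dropout = 0)
  med <- km_estimate(obs[obs$arm == "control", ])$median
  expect_lt(abs(med - 10), 0.3)
})

test_that("identical hazards in both arms give a null hazard ratio", {
  obs <- sim_two_arm(n = 2000, hr = 1, seed = 7)
  fit <- cox_marginal(obs, cluster = NULL)
  expect_gt(fit$ci_high, 1)
  expect_lt(fit$ci_low, 1)
})

test_that("inverse-CDF sampling matches the piecewise closed form at boundaries", {
  hs <- hazard_spec(c(0, 6, 12), list(control = c(0.08, 0.04, 0.10),
                                      experimental = c(0.08, 0.04, 0.10)))
  sp <- trial_sim_spec(5000, hs, accrual_months = 0, admin_censor_month = 1000,
                       dropout_rate = 0)
  obs <- simulate_trial(sp, seed = 11)
  n <- nrow(obs)
  for (b in c(6, 12, 18)) {
    Lam <- sum(pmin(pmax(b - c(0, 6, 12), 0), c(6, 6, Inf)) * c(0.08, 0.04, 0.10))
    S_true <- exp(-Lam)
    S_emp <- mean(obs$time > b)
    mc_se <- sqrt(S_true * (1 - S_true) / n)
    expect_lt(abs(S_emp - S_true), 3 * mc_se)
  }
})

test_that("delayed effect keeps the experimental arm at control hazards early", {
  obs <- sim_two_arm(n = 4000, hr = 0.5, seed = 3, delayed = 12,
                     accrual = 0, admin = 60, dropout = 0)
  # events before 12 months should be balanced; afterwards favor experimental
  early <- obs[obs$time <= 12, ]
  ratio_early <- sum(early$event[early$arm == "experimental"]) /
    sum(early$event[early$arm == "control"])
  expect_lt(abs(ratio_early - 1), 0.15)
  late_fit <- cox_marginal(obs[obs$time > 12, ], cluster = NULL)
  expect_lt(late_fit$hr, 0.8)
})

test_that("program-level frailty draws have the requested variance and degenerate cleanly", {
  specs0 <- lapply(1:10, function(i)
    trial_sim_spec(20, exponential_hazard(12, hr = 0.8), frailty_variance = 0,
                   trial_id = paste0("Z", i)))
  prog0 <- simulate_program(specs0, seed = 1)
  expect_true(all(prog0$frailties == 1))
  expect_equal(nrow(prog0$registry), 10)
  expect_equal(sum(prog0$registry$n_total), sum(table(prog0$ipd$trial_id)))

  specs <- lapply(1:20, function(i)
    trial_sim_spec(20, exponential_hazard(12, hr = 0.8), frailty_variance = 0.2,
                   trial_id = paste0("F", i)))
  prog <- simulate_program(specs, seed = 99)
  # 3 MC standard errors of a 20-draw variance estimate for gamma(var 0.2)
  expect_lt(abs(var(prog$frailties) - 0.2), 0.25)

  expect_error(simulate_program(list(), seed = 1), "at least one")
})

test_that("rendering yields the exact KM step function and risk counts", {
  obs <- data.frame(trial_id = "T", arm = "control", endpoint = "OS",
                    subgroup = "overall",
                    time = c(6, 6, 12, 12), event = c(1, 1, 0, 0))
  r <- render_km(obs, risk_interval = 12, coordinate_step = 6, jitter_sd = 0)
  expect_equal(r$risk$entries$n_at_risk, c(4L, 2L))
  p <- r$curve$points
  expect_equal(p$survival[p$time == 6], 0.5)
  expect_equal(p$survival[p$time == 0], 1)

  sim <- sim_two_arm(n = 100, seed = 5)
  cell <- sim[sim$arm == "control", ]
  r2 <- render_km(cell, risk_interval = 3, jitter_sd = 0)
  expect_equal(r2$risk$entries$n_at_risk[1], nrow(cell))
  km <- km_estimate(cell)
  at <- r2$curve$points$time %in% km$steps$time
  idx <- match(r2$curve$points$time[at], km$steps$time)
  expect_equal(r2$curve$points$survival[at], km$steps$surv[idx],
               tolerance = 1e-12)
})

test_that("rendering with jitter stays a valid survival curve", {
  sim <- sim_two_arm(n = 150, seed = 8)
  cell <- sim[sim$arm == "experimental", ]
  set.seed(21)
  r <- render_km(cell, risk_interval = 3, jitter_sd = 0.02)
  p <- r$curve$points
  expect_equal(p$survival[1], 1)
  expect_true(all(diff(p$survival) <= 1e-12))
  expect_true(all(p$survival >= 0 & p$survival <= 1))
})
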