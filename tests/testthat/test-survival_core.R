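test_that("KM estimates match hand product-limit computations", {
  all_cens <- data.frame(time = c(5, 8, 10), event = 0)
  km <- km_estimate(all_cens)
  expect_true(all(km$steps$surv == 1))
  expect_true(is.na(km$median))

  four <- data.frame(time = c(6, 6, 12, 12), event = c(1, 1, 0, 0))
  km4 <- km_estimate(four)
  expect_equal(km4$steps$surv[km4$steps$time == 6], 0.5)
  expect_equal(km4$median, 6)

  one <- data.frame(time = 3, event = 1)
  expect_equal(km_estimate(one)$steps$surv, 0)
})

test_that("KM value at the last event equals the product over prior drops", {
  for (seed in 1:5) {
    obs <- random_ipd(60, seed = seed)
    km <- km_estimate(obs)
    ev <- km$steps[km$steps$n_event > 0, ]
    expect_equal(ev$surv[nrow(ev)], prod(1 - ev$n_event / ev$n_risk),
                 tolerance = 1e-12)
  }
})

test_that("log-rank test agrees with the hand hypergeometric oracle", {
  d <- data.frame(time = c(1, 2, 3, 4), event = 1,
                  arm = c("control", "control", "experimental", "experimental"))
  lr <- logrank_test(d)
  oracle <- hand_logrank(d$time, d$event, as.integer(d$arm == "experimental"))
  expect_equal(lr$statistic, oracle, tolerance = 1e-9)

  same <- rbind(data.frame(time = c(2, 4, 6), event = c(1, 1, 0), arm = "control"),
                data.frame(time = c(2, 4, 6), event = c(1, 1, 0), arm = "experimental"))
  lr0 <- logrank_test(same)
  expect_lt(lr0$statistic, 1e-10)
  expect_equal(lr0$p_value, 1, tolerance = 1e-6)

  expect_error(logrank_test(d[d$arm == "control", ]), "two non-empty arms")
})

test_that("marginal Cox recovers a known hazard ratio and respects the null", {
  obs <- sim_two_arm(n = 4000, hr = 0.8, seed = 17)
  fit <- cox_marginal(obs, cluster = NULL)
  expect_lt(abs(fit$hr - 0.8), 0.05)
  expect_equal(fit$model, "marginal_cox")

  set.seed(9)
  perm <- obs
  perm$arm <- sample(perm$arm)
  fitp <- cox_marginal(perm, cluster = NULL)
  expect_true(fitp$ci_low < 1 && fitp$ci_high > 1)
})

test_that("cluster-robust and model-based errors agree for one large trial", {
  obs <- sim_two_arm(n = 3000, hr = 0.85, seed = 23)
  robust <- cox_marginal(obs, cluster = "trial_id")
  model <- cox_marginal(obs, cluster = NULL)
  expect_lt(abs(robust$se_log_hr / model$se_log_hr - 1), 0.2)
})

test_that("shared-frailty model degenerates to marginal Cox when frailty is absent", {
  specs <- lapply(1:6, function(i)
    trial_sim_spec(200, exponential_hazard(12, hr = 0.85), subgroup_fraction = 1,
                   frailty_variance = 0, accrual_months = 6,
                   admin_censor_month = 30, trial_id = paste0("Z", i)))
  prog <- simulate_program(specs, seed = 2)
  frail <- cox_shared_frailty(prog$ipd)
  marg <- cox_marginal(prog$ipd, cluster = NULL)
  expect_lte(frail$frailty_variance, 0.02)
  expect_lt(abs(frail$hr - marg$hr), 0.03)
})

test_that("shared-frailty model recovers theta and the treatment effect", {
  specs <- lapply(1:20, function(i)
    trial_sim_spec(300, exponential_hazard(14, hr = 0.8), subgroup_fraction = 1,
                   frailty_variance = 0.25, accrual_months = 12,
                   admin_censor_month = 40, trial_id = sprintf("F%02d", i)))
  prog <- simulate_program(specs, seed = 9)
  fit <- cox_shared_frailty(prog$ipd)
  expect_gte(fit$frailty_variance, 0.1)
  expect_lte(fit$frailty_variance, 0.45)
  expect_true(fit$ci_low <= 0.8 && 0.8 <= fit$ci_high)

  one <- sim_two_arm(n = 100, seed = 1)
  expect_error(cox_shared_frailty(one), ">= 2 trials")
})

test_that("subgroup analysis separates heterogeneous levels and flags degenerate ones", {
  mk_level <- function(hr, ids, cancer) {
    specs <- lapply(ids, function(i)
      trial_sim_spec(1000, exponential_hazard(12, hr = hr), subgroup_fraction = 1,
                     accrual_months = 6, admin_censor_month = 30,
                     trial_id = sprintf("S%02d", i), cancer_type = cancer))
    simulate_program(specs, seed = 100 + ids[1])
  }
  a <- mk_level(0.6, 1:2, "NSCLC")
  b <- mk_level(1.0, 3:4, "SCLC")
  ipd <- rbind(a$ipd, b$ipd)
  reg <- rbind(a$registry, b$registry)
  tab <- subgroup_analysis(ipd, reg, "cancer_type")
  expect_lt(tab$p_difference, 0.05)
  expect_lt(tab$levels$NSCLC$hr, tab$levels$SCLC$hr)

  # homogeneous levels: no spurious difference at this seed
  c2 <- mk_level(0.8, 5:6, "ESCC")
  d2 <- mk_level(0.8, 7:8, "GC")
  tab2 <- subgroup_analysis(rbind(c2$ipd, d2$ipd),
                            rbind(c2$registry, d2$registry), "cancer_type")
  expect_gt(tab2$p_difference, 0.05)

  # single level: difference test omitted with a flag
  tab3 <- subgroup_analysis(a$ipd, a$registry, "cancer_type")
  expect_true(is.na(tab3$p_difference))
  expect_match(tab3$flag, "omitted")
})
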