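test_that("subtraction identity and annihilation cases", {
  obs <- sim_two_arm(n = 50, seed = 1, subgroup_fraction = 0.5)
  empty <- obs[0, ]
  out <- subtract_subgroup(obs, empty)
  expect_equal(nrow(out), nrow(obs))

  known <- obs
  known$subgroup <- "pdl1_ge1"
  out2 <- subtract_subgroup(obs, known)
  expect_equal(nrow(out2), 0)
})

test_that("count conservation holds per arm", {
  obs <- sim_two_arm(n = 80, seed = 3, subgroup_fraction = 0.4)
  known <- obs[obs$subgroup == "pdl1_ge1", ]
  rem <- subtract_subgroup(obs, known)
  for (a in c("control", "experimental")) {
    expect_equal(sum(rem$arm == a) + sum(known$arm == a), sum(obs$arm == a))
  }
  expect_true(all(rem$subgroup == "pdl1_lt1"))
})

test_that("assignment matches brute-force enumeration on small instances", {
  set.seed(42)
  for (rep in 1:8) {
    m <- sample(2:6, 1); n <- sample(m:7, 1)
    cost <- matrix(runif(m * n, 0, 50), m, n)
    sq <- matrix(0, n, n)
    sq[seq_len(m), ] <- cost
    match <- icimeta:::.solve_assignment(sq)[seq_len(m)]
    achieved <- sum(cost[cbind(seq_len(m), match)])
    expect_equal(achieved, brute_force_min_cost(cost), tolerance = 1e-10)
    expect_equal(length(unique(match)), m)   # distinct assignment
  }
  # one 8x8 instance at the stated property bound
  cost8 <- matrix(runif(64, 0, 20), 8, 8)
  match8 <- icimeta:::.solve_assignment(cost8)
  expect_equal(sum(cost8[cbind(1:8, match8)]), brute_force_min_cost(cost8),
               tolerance = 1e-10)
})

test_that("subtracting a uniformly worse subgroup lifts the remainder curve", {
  # constructed: subgroup events early, remainder events late
  mk <- function(times, events, sg) data.frame(
    trial_id = "T", arm = "control", endpoint = "OS", subgroup = sg,
    time = times, event = events, stringsAsFactors = FALSE)
  worse <- mk(c(2, 3, 4, 5), 1, "pdl1_ge1")
  better <- mk(c(10, 12, 14, 16), c(1, 1, 0, 0), "overall")
  overall <- rbind(worse, better)
  overall$subgroup <- "overall"
  rem <- subtract_subgroup(overall, worse)
  km_all <- km_estimate(overall)
  km_rem <- km_estimate(rem)
  for (t in c(3, 6, 9, 12, 15)) {
    s_all <- km_survival_at(km_all, t)$surv
    s_rem <- km_survival_at(km_rem, t)$surv
    expect_gte(s_rem, s_all - 1e-12)
  }
})

test_that("subtracted remainder recovers the unreported subgroup hazard ratio", {
  sp <- trial_sim_spec(600, exponential_hazard(12, hr_lt1 = 0.7, hr_ge1 = 0.6),
                       subgroup_fraction = 0.4, accrual_months = 6,
                       admin_censor_month = 30, dropout_rate = 0.005)
  sim <- simulate_trial(sp, seed = 11)
  rec_o <- list(); rec_k <- list()
  for (a in c("control", "experimental")) {
    oa <- sim[sim$arm == a, ]
    ka <- oa[oa$subgroup == "pdl1_ge1", ]
    ro <- render_km(oa, 3, 1, 0, subgroup_label = "overall")
    rk <- render_km(ka, 3, 1, 0, subgroup_label = "pdl1_ge1")
    rec_o[[a]] <- reconstruct_ipd(ro$curve, ro$risk)$observations
    rec_k[[a]] <- reconstruct_ipd(rk$curve, rk$risk)$observations
  }
  rem <- subtract_subgroup(do.call(rbind, rec_o), do.call(rbind, rec_k))
  truth <- sim[sim$subgroup == "pdl1_lt1", ]
  expect_equal(nrow(rem), nrow(truth))
  # close to the same-sample truth, and to the generating HR of 0.7
  expect_lt(abs(log(ref_cox_hr(rem)) - log(ref_cox_hr(truth))), 0.1)
  expect_lt(abs(log(ref_cox_hr(rem)) - log(0.7)), 0.25)
})

test_that("subtraction refuses structurally invalid inputs", {
  obs <- sim_two_arm(n = 20, seed = 2, subgroup_fraction = 0.5)
  big <- rbind(obs, obs)
  big$subgroup <- "pdl1_ge1"
  expect_error(subtract_subgroup(obs, big), "larger than overall")
  other <- obs
  other$trial_id <- "OTHER"
  other$subgroup <- "pdl1_ge1"
  expect_error(subtract_subgroup(obs, other), "same trial")
})

test_that("Monte Carlo error limits behave across iteration counts", {
  template <- trial_sim_spec(150, exponential_hazard(12, hr_lt1 = 0.7, hr_ge1 = 0.6),
                             subgroup_fraction = 0.45, accrual_months = 6,
                             admin_censor_month = 30)
  one <- estimate_error_limits(template, n_iterations = 1, seed = 5)
  expect_equal(one$deviation_interval_95[1], one$deviation_interval_95[2])
  expect_equal(abs(one$deviations), one$mean_abs_log_hr_deviation)

  el <- estimate_error_limits(template, n_iterations = 8, seed = 5)
  expect_equal(el$n_iterations, 8)
  expect_lte(el$deviation_interval_95[1], el$deviation_interval_95[2])
  expect_true(is.finite(el$mean_abs_log_hr_deviation))
  expect_gte(el$mean_abs_log_hr_deviation, 0)

  bad <- trial_sim_spec(50, exponential_hazard(12), subgroup_fraction = 0)
  expect_error(estimate_error_limits(bad, n_iterations = 2, seed = 1),
               "strictly inside")
})
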