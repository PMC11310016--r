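test_that("curve preprocessing cleans digitization artifacts", {
  cv <- digitized_curve("T", "control", "OS", "overall",
                        c(0, 4, 8, 12), c(1.0, 0.62, 0.64, 0.50))
  out <- preprocess_curve(cv)
  # pool-adjacent-violators on the decreasing constraint
  expect_equal(out$points$survival, c(1.0, 0.63, 0.63, 0.50))

  cv2 <- digitized_curve("T", "control", "OS", "overall",
                         c(0, 5, 10), c(1.03, 0.8, 0.6))
  expect_equal(preprocess_curve(cv2)$points$survival[1], 1)

  cv3 <- digitized_curve("T", "control", "OS", "overall",
                         c(3, 6), c(0.9, 0.7))
  out3 <- preprocess_curve(cv3)
  expect_equal(out3$points$time[1], 0)
  expect_equal(out3$points$survival[1], 1)

  valid <- digitized_curve("T", "control", "OS", "overall",
                           c(0, 5, 10), c(1, 0.8, 0.6))
  expect_equal(preprocess_curve(valid)$points, valid$points)

  expect_error(preprocess_curve(
    digitized_curve("T", "control", "OS", "overall", c(3, 3), c(1, 1))),
    "2 distinct")
})

test_that("hand-solvable reconstructions are decoded exactly", {
  cv <- digitized_curve("T", "control", "OS", "overall",
                        c(0, 6, 12), c(1, 0.5, 0.5))
  rt <- risk_table("T", "control", "OS", "overall", c(0, 12), c(4, 2))
  rec <- reconstruct_ipd(cv, rt)
  expect_equal(rec$n_events_assigned, 2)
  expect_equal(rec$n_censored_assigned, 2)
  expect_equal(sort(rec$observations$time[rec$observations$event == 1]), c(6, 6))
  expect_equal(sort(rec$observations$time[rec$observations$event == 0]), c(12, 12))

  flat <- digitized_curve("T", "control", "OS", "overall",
                          c(0, 6, 12), c(1, 1, 1))
  rtf <- risk_table("T", "control", "OS", "overall", c(0, 12), c(10, 10))
  recf <- reconstruct_ipd(flat, rtf)
  expect_equal(recf$n_events_assigned, 0)
  expect_equal(recf$n_censored_assigned, 10)
  expect_true(all(recf$observations$time == 12))
})

test_that("reconstruction conserves patients and matches at-risk targets", {
  for (seed in 1:3) {
    sim <- sim_two_arm(n = 120, hr = 0.7, seed = seed)
    cell <- sim[sim$arm == "control", ]
    r <- render_km(cell, risk_interval = 6, jitter_sd = 0)
    rec <- reconstruct_ipd(r$curve, r$risk)
    expect_equal(rec$n_events_assigned + rec$n_censored_assigned, nrow(cell))
    d <- rec$diagnostics
    d <- d[!is.na(d$target_n_risk), ]
    expect_lte(max(abs(d$achieved_n_risk - d$target_n_risk)), 1)
  }
})

test_that("noiseless reconstruction reproduces the input curve at every coordinate", {
  sim <- sim_two_arm(n = 80, hr = 0.8, seed = 13)
  cell <- sim[sim$arm == "experimental", ]
  r <- render_km(cell, risk_interval = 1, coordinate_step = 1, jitter_sd = 0)
  rec <- reconstruct_ipd(r$curve, r$risk)
  km <- km_estimate(rec$observations)
  ev <- km$steps[km$steps$n_event > 0, ]
  S_rec <- vapply(r$curve$points$time, function(t) {
    below <- ev$time <= t
    if (!any(below)) 1 else ev$surv[max(which(below))]
  }, numeric(1))
  expect_lt(max(abs(S_rec - r$curve$points$survival)), 1e-6)
})

test_that("simulate -> render -> reconstruct round trip recovers KM summaries", {
  sim <- sim_two_arm(n = 250, hr = 0.7, seed = 7, accrual = 6, admin = 30,
                     dropout = 0.01)
  rec <- render_and_reconstruct(sim, risk_interval = 3)
  for (a in c("control", "experimental")) {
    med_true <- km_estimate(sim[sim$arm == a, ])$median
    med_rec <- km_estimate(rec[rec$arm == a, ])$median
    expect_lt(abs(med_rec - med_true), 0.5)
  }
  expect_lt(abs(log(ref_cox_hr(rec)) - log(ref_cox_hr(sim))), 0.05)
})

test_that("reconstruction error grows with digitization noise", {
  jitters <- c(0, 0.005, 0.02)
  err <- numeric(length(jitters))
  for (j in seq_along(jitters)) {
    tot <- 0
    for (seed in 1:16) {
      sim <- sim_two_arm(n = 300, hr = 0.75, seed = seed)
      set.seed(5000 + seed)      # fixed renderer noise stream per cell pair
      rec <- render_and_reconstruct(sim, jitter_sd = jitters[j])
      tot <- tot + abs(log(ref_cox_hr(rec)) - log(ref_cox_hr(sim)))
    }
    err[j] <- tot
  }
  expect_true(all(diff(err) >= 0))
})

test_that("QC report compares reconstructed and reference summaries", {
  sims <- lapply(1:4, function(i)
    sim_two_arm(n = 150, hr = 0.6 + 0.1 * i, seed = 20 + i,
                trial_id = paste0("T", i)))
  refs <- do.call(rbind, lapply(sims, function(s)
    data.frame(trial_id = s$trial_id[1], hr = ref_cox_hr(s),
               median_experimental = km_estimate(s[s$arm == "experimental", ])$median,
               median_control = km_estimate(s[s$arm == "control", ])$median)))
  # identity comparison: each trial against its own summaries
  ipd <- do.call(rbind, sims)
  qc <- validate_reconstruction(split(ipd, ipd$trial_id), refs)
  expect_false(qc$correlation_omitted)
  expect_equal(unname(qc$pearson["log_hr"]), 1, tolerance = 1e-10)
  expect_true(all(abs(qc$table$log_hr_deviation) < 1e-10))

  # fewer than 3 pairs: correlation omitted and flagged
  qc2 <- validate_reconstruction(split(ipd, ipd$trial_id)[1:2], refs[1:2, ])
  expect_true(qc2$correlation_omitted)
  expect_true(all(is.na(qc2$pearson)))
})
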