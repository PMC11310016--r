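# Shared simulation fixtures, built in code at test time.

sim_two_arm <- function(n = 300, hr = 0.8, median_control = 12, seed = 1,
                        subgroup_fraction = 1, frailty_variance = 0,
                        accrual = 12, admin = 36, dropout = 0.005,
                        trial_id = "T1", delayed = 0) {
  spec <- trial_sim_spec(n, exponential_hazard(median_control, hr = hr),
                         subgroup_fraction = subgroup_fraction,
                         frailty_variance = frailty_variance,
                         accrual_months = accrual, admin_censor_month = admin,
                         dropout_rate = dropout,
                         delayed_effect_month = delayed, trial_id = trial_id)
  simulate_trial(spec, seed = seed)
}

render_and_reconstruct <- function(obs, risk_interval = 3, coordinate_step = 1,
                                   jitter_sd = 0) {
  out <- list()
  for (a in c("control", "experimental")) {
    cell <- obs[obs$arm == a, ]
    r <- render_km(cell, risk_interval = risk_interval,
                   coordinate_step = coordinate_step, jitter_sd = jitter_sd,
                   subgroup_label = "overall")
    out[[a]] <- reconstruct_ipd(r$curve, r$risk)$observations
  }
  do.call(rbind, out)
}

random_ipd <- function(n = 100, seed = 1) {
  set.seed(seed)
  if (n == 0)
    return(data.frame(trial_id = character(0), arm = character(0),
                      endpoint = character(0), subgroup = character(0),
                      time = numeric(0), event = integer(0)))
  data.frame(trial_id = sample(c("A", "B"), n, TRUE),
             arm = sample(c("control", "experimental"), n, TRUE),
             endpoint = "OS",
             subgroup = sample(c("pdl1_lt1", "pdl1_ge1", "overall"), n, TRUE),
             time = round(stats::rexp(n, 0.08), 6),
             event = rbinom(n, 1, 0.7), stringsAsFactors = FALSE)
}
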