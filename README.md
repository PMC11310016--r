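# icimeta

Pooled survival analysis of first-line PD-1/PD-L1 checkpoint-inhibitor
trials in the **PD-L1 < 1%** population.

Randomized trials of PD-1/PD-L1 blockade usually publish Kaplan–Meier
curves for the intention-to-treat and PD-L1-positive populations, while the
PD-L1-low subgroup — often a third or more of the randomized patients — goes
unreported. `icimeta` provides the full analysis chain needed to quantify
the treatment effect in that unreported subgroup from what *is* published:

1. **IPD reconstruction** (`reconstruct_ipd`) — a Guyot-type decoder turns
   digitized KM coordinates plus a number-at-risk table back into
   individual patient data. Within each risk-table interval it solves
   jointly for event and censoring counts so that the product-limit curve of
   the reconstruction reproduces the published drops and the count still at
   risk matches the table; an exact integer-fit pass recovers clean curves
   to machine precision.
2. **Subgroup subtraction** (`subtract_subgroup`) — the unreported subgroup
   is derived by removing the reported subgroup from the overall
   population via minimal-cost bipartite matching on follow-up time and
   event status (Hungarian algorithm, event-status mismatches soft-penalized),
   with Monte Carlo error limits (`estimate_error_limits`).
3. **One-stage pooled analysis** — log-rank test, marginal Cox with
   cluster-robust errors, and a gamma shared-frailty Cox model
   (`cox_shared_frailty`) whose frailty variance is estimated by outer
   profile optimization; forest-style subgroup machinery with Cochran's Q
   interaction tests.
4. **Bayesian time-varying hazard ratio** (`fit_piecewise_tvhr`) — a
   hierarchical piecewise-exponential model with hazards constant in
   3-month segments up to 60 months, each segment carrying its own
   baseline hazard and treatment effect, trial random intercepts, MCMC
   sampling and split-chain Rhat diagnostics, summarized by an
   event-weighted average hazard ratio.
5. **RMST** (`rmst_difference`, `rmst_scan`) — restricted mean survival
   time differences with endpoint-specific truncation (24 months OS,
   12 months PFS, shortened to the minimum of the largest observed times),
   and a truncation scan locating the earliest significant difference.
6. **Clinical-benefit grading** (`grade_benefit`) — a simplified
   ESMO-MCBS-style rule: gains of ≥ 2 months (control median ≤ 12), ≥ 3
   months (12–24), or ≥ 10 percentage points of 2-year OS (median not
   reached), each requiring the upper HR confidence limit below 1.
7. **Aggregate meta-analysis** (`pool_random_effects`, `eggers_test`,
   `compare_ipd_vs_total`) — DerSimonian–Laird random-effects pooling of
   published and IPD-derived hazard ratios, Egger regression for
   publication bias, and the representativeness comparison of
   IPD-available trials against the total evidence base.

A synthetic multi-trial generator (`simulate_trial`, `simulate_program`,
`render_km`) with piecewise-exponential hazards, a latent PD-L1 subgroup
mixture, trial-level gamma frailty, optional delayed treatment effects,
accrual and administrative censoring, and a published-figure-style renderer
gives every stage a known ground truth.

The bundled registry (`bundled_registry()`) covers the 49 first-line phase 3
trials of the underlying evidence base: 37,036 randomized patients, with
the PD-L1 < 1% share per trial ranging from 14.3% to 85.7%.

## Worked example

Simulate a six-trial program in which the PD-L1 < 1% subgroup (40% of
patients) has a true hazard ratio of 0.75, publish only the overall and
PD-L1 ≥ 1% curves, reconstruct and subtract the unreported subgroup, and
analyze it:

```r
library(icimeta)

reg <- bundled_registry()
specs <- lapply(1:6, function(i)
  trial_sim_spec(250, exponential_hazard(14, hr_lt1 = 0.75, hr_ge1 = 0.65),
                 subgroup_fraction = 0.4, frailty_variance = 0.1,
                 trial_id = sprintf("SIM-%02d", i)))
prog <- simulate_program(specs, seed = 42)

rec <- list()
for (tid in unique(prog$ipd$trial_id)) for (a in c("control", "experimental")) {
  cell <- prog$ipd[prog$ipd$trial_id == tid & prog$ipd$arm == a, ]
  ov <- render_km(cell, risk_interval = 3, subgroup_label = "overall")
  kn <- render_km(cell[cell$subgroup == "pdl1_ge1", ], risk_interval = 3)
  overall <- reconstruct_ipd(ov$curve, ov$risk)$observations
  known   <- reconstruct_ipd(kn$curve, kn$risk)$observations
  rec[[paste(tid, a)]] <- subtract_subgroup(overall, known)
}
lt1 <- do.call(rbind, rec)          # the derived PD-L1 < 1% population

cox_shared_frailty(lt1, prog$registry, "cancer_type")
#> shared_frailty_cox: HR 0.778 (95% CI 0.678-0.894), p = 0.0003848 [n = 1193, events = 809]
#>   frailty variance theta = 0.0551

rmst_difference(lt1, choose_truncation(lt1, "OS"))
#> RMST (tau = 24 months): 16.61 vs 14.63; difference 1.98 (0.99-2.97), p = 9.296e-05

marg <- cox_marginal(lt1)
grade_benefit(km_estimate(lt1[lt1$arm == "control", ])$median,
              km_estimate(lt1[lt1$arm == "experimental", ])$median,
              marg$ci_high)
#> Clinical benefit: grade 3 (meaningful) (rule: median_12to24)
```

The frailty-adjusted hazard ratio (0.78) recovers the generating subgroup
effect (0.75) from reconstructed-and-subtracted data alone; the RMST
difference of about 2.0 months over 24 months and the control median of
15.2 months place the effect in the "grade 3 (meaningful)" band of the
simplified benefit scale.

The same chain runs as a configured pipeline:

```r
run_pipeline("all", system.file("extdata", "demo_config.yaml", package = "icimeta"),
             out_dir = "demo_out")
```

or from a shell via `inst/cli/icimeta.R`.

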