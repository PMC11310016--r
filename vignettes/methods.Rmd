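---
title: "Methods: reconstructing and pooling unreported PD-L1-low subgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing and pooling unreported PD-L1-low subgroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

First-line trials of PD-1/PD-L1 blockade report survival for the
intention-to-treat and PD-L1-positive populations; the PD-L1 < 1% subgroup
is frequently left without curves of its own. `icimeta` implements the
chain that turns the published material — digitized Kaplan–Meier
coordinates, number-at-risk tables, and aggregate hazard ratios — into a
patient-level analysis of that unreported subgroup. This vignette records
the statistical models, the numerical choices, and the design decisions
that were genuinely open.

All times are months; conversions to years are explicit
(`months_to_years`) and never implicit.

## IPD reconstruction

`reconstruct_ipd()` decodes one (trial, arm) cell from a preprocessed curve
and its risk table. Within the interval between consecutive risk-table
times the decoder must place events (at the published drop times) and
censorings (whose times are not identified by the figure) so that

* the product-limit estimate of the reconstruction reproduces the
  published survival value at every coordinate, and
* the count still at risk at the next risk-table time equals the printed
  value.

Two solvers run in sequence:

1. **Exact integer fit.** Walking the coordinates in order, the decoder
   chooses the smallest number of censorings before each drop that makes
   the implied event count `d = n (1 - S_k / S)` integral. Any such fit
   reproduces the published value exactly, because the product-limit
   update then gives `S * (1 - d/n) = S_k` identically; leftover removals
   become end-of-interval censorings so the at-risk target is met exactly.
   On curves rendered without noise this pass recovers the KM function to
   machine precision (the suite asserts `1e-6`).
2. **Midpoint-grid fixed point.** When no exact fit exists (noisy
   digitization), the interval censoring count is iterated — censor times
   on the uniform midpoint grid of the interval, per-coordinate event
   demands real-valued during solving, interval totals forced integral by
   largest-remainder rounding — until the at-risk match is exact or a fixed
   point is reached (25 iterations; the closest match and its deviation are
   recorded in the diagnostics).

After the last risk-table time, remaining patients are censored at the
last coordinate time; when a reported total event count is supplied, a
final pass redistributes events globally by largest remainder to match it
(this pass uses the midpoint-grid solver throughout). A curve whose risk
table has only the time-0 entry falls back to censoring at the curve end
and is flagged. The KM median convention throughout the package is *the
first time the estimate reaches 0.5 or below*, `NA` meaning not reached.

`validate_reconstruction()` mirrors the representativeness QC applied to
published trials: per-trial deviations of the hazard ratio and per-arm
medians, with Pearson correlations per summary family when at least three
reference pairs are available.

## Subgroup subtraction

`subtract_subgroup()` removes a reported subgroup from the overall
population per randomized arm. Each subgroup patient is matched to a
distinct overall patient by minimal-cost bipartite assignment with cost
`|Δ time| + penalty · [event flags differ]`; the penalty defaults to ten
times the maximum observed follow-up, so cross-status matches are a last
resort rather than forbidden — degenerate status counts still solve. The
assignment is solved by an `O(n³)` Hungarian algorithm (Rcpp); ties are
broken deterministically by a stable sort on time, event, input order.
Matching never crosses arms, because subgroups are nested within
randomization. `estimate_error_limits()` repeats
simulate → render → reconstruct → subtract with fresh seeds and reports the
mean absolute log-HR deviation against the simulation's true subgroup plus
the 2.5/97.5 percentile interval; the published workflow uses 1,000
iterations, and the trial template for the perturbation is an explicit
argument rather than an implicit default.

## One-stage pooled analysis

Kaplan–Meier estimation, the log-rank test and Cox models are delegated to
the `survival` package with Efron tie handling — the better choice under
the heavy ties that grid-timed reconstruction produces. The marginal Cox
model uses standard errors robust to within-trial clustering (per-
observation sandwich when only one trial is present, where a one-cluster
grouped sandwich would degenerate). The shared-frailty model places a
mean-1 gamma frailty on trials. Its variance θ is estimated by **outer
profile optimization**: each candidate θ gets an inner penalized fit and
the EM-corrected marginal likelihood is maximized over θ by golden-section
search to `1e-5`, with the θ = 0 boundary accepted when the profile is
non-increasing there. (The default outer EM iteration of the penalized
fitter proved unreliable on simulated programs — it overstated θ several-
fold — which this profile search corrects; parameter recovery is asserted
in the suite at θ = 0.25 with 20 trials of 300 patients per arm.)
Covariates come from the trial registry (cancer type, drug class,
control-arm category as categoricals); reference levels are the most
frequent category and constant columns are dropped, both for determinism.
The subgroup-difference test is Cochran's Q on per-level log hazard ratios
with inverse-variance weights — the standard forest-plot interaction test;
the source analyses report a "p for subgroup difference" without naming
one.

## Bayesian time-varying hazard ratio

The hierarchical model assumes hazards constant within 3-month segments,
truncated at 60 months. Each segment has its own baseline log hazard and
its own treatment effect; trial-level covariates and a trial random
intercept complete the linear predictor. Because covariates are
trial-level, the piecewise-exponential likelihood collapses to Poisson
counts with log-exposure offsets on (trial, arm, segment) cells, which is
the form sampled (JAGS, 4 chains; defaults 1,000 retained iterations after
500 warm-up per chain — the chain count makes split-Rhat possible).
Priors are weakly informative and explicit: Normal(0, 2.5²) on segment
treatment effects and covariate effects, Normal(0, 5²) on baseline log
hazards, half-Normal(0, 1) on the random-intercept SD. The random
intercepts are **sum-to-zero centered** (baselines absorb the mean):
without centering, the additive confounding between segment baselines and
trial intercepts stalls mixing and split-Rhat stays above 1.1 at these
run lengths. Segments with zero exposure are flagged and remain
prior-dominated rather than being dropped. Convergence is judged by
split-chain Rhat < 1.1 per monitored parameter; non-convergence raises a
warning, never a silent acceptance. The average HR is the per-draw
weighted geometric mean of segment HRs; both event-count weights (the
default, recorded in the output) and equal weights are implemented, since
the source describes an average adjusted HR without stating the weighting.

## RMST and benefit grading

Per-arm RMST is the area under the KM curve to τ with the standard
nonparametric variance (each event time contributes its squared residual
area times `d / (n (n − d))`); the difference carries a normal
approximation CI. This estimator is computed directly rather than through
`survfit`'s restricted-mean printout, which refuses truncation times below
the smallest observed time and would make the no-event edge case (RMST
exactly τ) an error. Truncation defaults are 24 months for OS and 12 for
PFS, shortened to the minimum over arms of the largest observed time.
`rmst_scan()` reports the earliest grid τ whose CI excludes zero.

The simplified benefit scale is stated for OS only, so applying it to PFS
requires an explicit override. "10% increase in 2-year OS" is read as 10
absolute percentage points (the ESMO-MCBS convention). Meaningful outcomes
carry the single label "grade 3 (meaningful)" — the printed scale cannot
separate grades 3 and 4, and no unprinted grade-4 rule is invented. A
control median above 24 months with medians reached falls outside the
stated bands and returns an explicit "rule undefined" outcome instead of a
guess. The predictive value of PD-L1 expression is
`log(HR_{<1%} / HR_{≥1%})`.

## Aggregate meta-analysis

Pooling is DerSimonian–Laird on the log-HR scale (via `metafor`), with
standard errors derived from the reported 95% limits; DL is the field
default where the source states only "random-effects model". Stratified
pooling adds a between-stratum Q test on stratum means. Egger's test is
the classical weighted regression of standardized effect on precision;
identical precisions make that regression degenerate and are reported as a
symmetric (zero-intercept) funnel rather than an error. The
IPD-representativeness comparison pools the IPD-available subset and the
total set and compares them with a one-degree-of-freedom Q; the source
does not name its comparison test, so this choice is documented here.
Significance is two-tailed 0.05 throughout.

## The synthetic generator

`simulate_trial()` draws event times from a piecewise-exponential model by
inverse-CDF sampling, with a latent PD-L1 < 1% / ≥ 1% mixture, uniform
accrual over `accrual_months`, administrative censoring at
`admin_censor_month − entry`, exponential dropout, and an optional delayed
effect (experimental-arm hazards equal control before onset — this is the
mechanism behind the late separation that motivates the RMST scan and
TVHR model). `simulate_program()` draws one mean-1 gamma frailty per trial
(shared by both arms, acting on the hazard scale, matching the analysis
model). `render_km()` degrades exact IPD into figure-style inputs: the KM
step function sampled at every event time plus a monthly grid, optional
truncated-Gaussian jitter re-projected to a monotone curve, and exact
at-risk counts at quarterly intervals by default — the granularity at which
published figures print risk tables.

Default study conditions used by the suite and the acceptance script:
trials of 200–300 patients per arm, control medians of 12–14 months,
hazard ratios spanning 0.5–1.2, quarterly risk tables, monthly coordinate
grids, frailty variance 0.1–0.25, 12-month accrual with administrative
censoring at 36–40 months and ~0.5%/month dropout — the scale of the real
trial program in the bundled registry. The generator emulates neither
competing risks, informative censoring, nor patient-level covariates, so
passing tests demonstrate correctness of the decoding and modeling chain
under these mechanisms — not robustness to, say, informative dropout in
real trials.

## Problem sizes and reproducibility

Monte Carlo checks in the suite use fixed seeds and sizes chosen so
sampling error is well below the asserted tolerances: n = 5,000 for
closed-form median recovery, n = 4,000 for Cox and RMST closed forms,
20 × 300-per-arm trials for reconstruction-fidelity correlations,
10 × 200-per-arm trials for the TVHR convergence check, and 16 fixed-seed
replicates for the jitter-monotonicity property. The pipeline derives a
per-stage RNG substream from the global seed keyed by stage name, so any
stage can be rerun without perturbing the others.

## Known limitations

* Censor times inside a risk-table interval are not identified by the
  published material; both solvers place them on deterministic grids, so
  patient-level times (though not KM summaries) carry interval-scale
  error.
* Subtraction error limits are reported separately and are not propagated
  into downstream confidence intervals.
* The frailty profile search assumes a unimodal marginal likelihood in θ
  on (0, 5]; multimodal profiles would need a grid refinement.
* The TVHR model treats covariates as trial-level; patient-level
  modifiers are outside what reconstruction can recover.
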