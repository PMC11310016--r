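# Demo configuration: a small synthetic trial program exercising the full
# simulate -> render -> reconstruct -> subtract -> validate -> pool -> tvhr
# -> rmst -> grade -> meta chain.
seed: 7
endpoint: OS
simulate:
  n_trials: 4
  n_per_arm: 150
  median_control: 12        # months; control-arm exponential median
  hr_lt1: 0.75              # treatment hazard ratio in the PD-L1 < 1% subgroup
  hr_ge1: 0.65              # treatment hazard ratio in the PD-L1 >= 1% subgroup
  subgroup_fraction: 0.4    # latent share of PD-L1 < 1% patients
  frailty_variance: 0.05    # variance of the mean-1 gamma trial frailty
  accrual_months: 12
  admin_censor_month: 36
  dropout_rate: 0.005
render:
  risk_interval: 3          # months between number-at-risk entries
  coordinate_step: 1        # months between curve coordinates
  jitter_sd: 0              # digitization noise on the survival scale
tvhr:
  chains: 4
  iterations: 1000
  warmup: 500
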