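# Default scenario for the packaged cardiometabolic model.
#
# Values tagged ILLUSTRATIVE are package demonstration defaults, not
# literature estimates: the source analysis publishes only the 23.5%
# baseline hypertension prevalence and does not publish intervention
# effect magnitudes.  Replace them with program-specific values for any
# real evaluation.
start_age: 40
horizon: 5
discount_rate: 0.03
population: 4461
baseline_distribution:        # ILLUSTRATIVE except HTN = 0.235
  Healthy: 0.40
  Obesity: 0.20
  PreDM: 0.10
  PreHTN: 0.03
  HTN: 0.235
  DM: 0.035
program_cost_per_member_year: 720
program_cost_total_override: ~
intervention_rrr:             # ILLUSTRATIVE relative-risk multipliers
  Healthy->Obesity: 0.7
  Healthy->PreDM: 0.7
  Healthy->PreHTN: 0.7
  Obesity->PreDM: 0.7
  Obesity->DM: 0.7
  PreDM->DM: 0.7
  PreDM->HighRiskDM: 0.7
  PreHTN->HTN: 0.7
  HTN->HTN2: 0.7
  DM->HighRiskDM: 0.7
  DM_HTN->HighRiskDM: 0.7
  ANY->CAD: 0.85
  ANY->MI: 0.85
  ANY->CHF: 0.85
  ANY->Stroke: 0.85
remission_probs: {}           # intervention-arm improvement edges, off by default
engagement_tier: standard     # label only; not used numerically
savings_split:
  medication_fraction: 0.30   # ILLUSTRATIVE reporting split
half_cycle_correction: false
psa:
  n_iter: 10000
  seed: 20260418
  percentiles: [0.025, 0.975]
  rrr_sigma: 0.1
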