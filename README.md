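# lbcroi

Markov cohort cost-effectiveness and return-on-investment modelling for
lifestyle and behavioral care (LBC) programs targeting cardiometabolic
disease.

## The problem

Employers and health plans that fund coaching-based chronic-disease
programs need to know whether the program pays for itself: how much
medical spending it avoids, how much health it buys, and what the return
per dollar invested is. `lbcroi` answers this with an annual-cycle
**cohort state-transition (Markov) model**: a closed cohort of members
occupies mutually exclusive health states (healthy, obesity,
pre-diabetes, pre-hypertension, hypertension and stage-2 hypertension,
diabetes, ischemic heart disease, myocardial infarction, congestive
heart failure, stroke, composite states such as diabetes +
hypertension, and high-risk diabetes, plus an implicit absorbing death
state) and moves between them once per year according to a transition
probability matrix. Death is age-specific, taken from a life table.

Each state *s* carries an annual direct medical cost *c_s* (USD) and a
utility weight *u_s* ∈ [0, 1]. Over a horizon of *T* annual cycles with
discount rate *r*, an arm accrues per member

- discounted cost  Σ_t x_t·c · (1+r)^−t  (+ program cost per alive
  member-year in the intervention arm), and
- discounted QALYs Σ_t x_t·u · (1+r)^−t,

where x_t is the state-occupancy vector at the start of cycle *t*. The
intervention arm applies relative-risk multipliers (RRR < 1) to named
progression/incidence edges and may add remission edges out of the
reversible states (obesity, diabetes, hypertension). Comparing arms
yields

    net savings = (medication savings + services savings) − program costs
    ROI         = net savings / program costs
    QALY gain   = QALYs_intervention − QALYs_control   (× 365 = days of full health)

Uncertainty is handled by probabilistic sensitivity analysis (Monte
Carlo over beta distributions for probabilities and utilities, gamma for
costs, lognormal for relative risks) and one-way tornado analysis.

## Worked example

Applying the economics layer to five-year per-member arm totals of
$41,431 (treated, program cost included) versus $47,834 (control), with
4.7 vs 4.6 QALYs, a 4,461-member population and total program costs of
$4,371,780:

```r
library(lbcroi)
cfg <- scenario_config(population = 4461, horizon = 5,
                       program_cost_total_override = 4371780)
control <- cohort_trace_totals("control", 5, total_cost = 47834, total_qaly = 4.6)
treated <- cohort_trace_totals("intervention", 5, total_cost = 41431,
                               total_qaly = 4.7, program_cost = 4371780 / 4461)
econ_summary(treated, control, cfg)
#> Economic summary over 5 years, population 4,461
#>  metric                          treated      control      difference
#>  Total cost per member (5 years) $     41,431 $     47,834 $     6,403
#>  Annual cost per member          $      8,286 $      9,567 $     1,281
#>  Monthly cost per member         $        691 $        797 $       106
#>  Population total cost           $184,823,691 $213,387,474 $28,563,783
#> Savings decomposition: medication $9,880,669 + services $23,054,894 - program $4,371,780 = $28,563,783
#> QALYs: 4.7000 treated vs 4.6000 control (gain 0.1000 = 36.5 days)
#> ROI: 6.53
```

The program saves $6,403 per member ($106/month), buys 0.1 QALY (36.5
days of full health), and returns $6.53 per program dollar.

A full simulation from the packaged default scenario (whose baseline
mix and effect sizes are *illustrative*, flagged in the scenario file):

```r
res <- run_scenario(lbc_default_scenario())
res$summary$roi        # -0.888 with the illustrative defaults
res$summary$qaly_gain  # 0.0116
```

With the illustrative effect sizes the program does **not** break even —
the per-member medical savings are smaller than the $720/year program
cost. Real evaluations must supply program-specific relative-risk
reductions and a baseline distribution in the scenario YAML.

## Command line

```sh
lbcroi synth   --out scenario_dir --prevalence 'HTN=0.235'
lbcroi run     --config scenario_dir/scenario.yaml --out results/
lbcroi psa     --config scenario_dir/scenario.yaml --out results/ --iterations 1000 --seed 7
lbcroi tornado --config scenario_dir/scenario.yaml --ranges ranges.yaml --out results/
```

(`lbcroi` is installed under `exec/` in the package library; call it via
`Rscript $(Rscript -e 'cat(system.file("exec","lbcroi",package="lbcroi"))') ...`
or put it on your PATH.) Outputs are CSV/JSON files plus a
reproducibility manifest; flags override the config file.

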