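---
title: "Model and methods: the lbcroi cohort cost-effectiveness engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: the lbcroi cohort cost-effectiveness engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbcroi)
```

## The model

`lbcroi` implements an annual-cycle cohort state-transition (Markov)
model of cardiometabolic disease progression. A closed cohort occupies
mutually exclusive health states; once per one-year cycle the occupancy
vector is multiplied by a row-stochastic transition matrix. The model is
memoryless: next-cycle probabilities depend only on the current state.
Comorbidity is represented by explicit composite states (e.g. diabetes +
hypertension) rather than by overlapping flags, which keeps states
mutually exclusive and lets composite states carry their own costs,
utilities and risks. Death is an implicit absorbing state with cost 0
and utility 0; its column is filled from an age-indexed life table, so
background mortality rises as the cohort ages through the horizon.

Each alive state carries an annual direct medical cost (USD/year) and a
utility weight in [0, 1]. Per cycle and per member the engine accrues
`occupancy · cost` and `occupancy · utility`, each discounted by
`1/(1+r)^t`. The intervention arm differs from the modeled usual-care
arm in exactly three ways: relative-risk multipliers in (0, 1] applied
multiplicatively to named progression/incidence edges, optional
remission edges out of the reversible states (obesity, diabetes,
hypertension), and a program cost accrued per alive member-year and
discounted like any other cost. Everything else — tables, life table,
discounting — is shared, so arm differences are attributable to the
intervention parameters alone.

### Cycle accounting

Costs and QALYs accrue on **start-of-cycle occupancy**, with no
half-cycle correction in the base case; the reported aggregate
identities (annual ≈ total/horizon) presuppose exactly this convention.
A `half_cycle_correction` switch (off by default) accrues on the mean of
start- and end-of-cycle occupancy instead, for users who prefer the
mid-cycle assumption. Cycle 0 is discounted at factor 1.

### Wildcard transition rows

Acute-event rows are written `ANY -> MI`, `ANY -> Stroke`, etc. A
wildcard row expands to every alive from-state — including the healthy
reference state, which we consider the natural reading of
"any" — except (a) the target state itself (no self-loop via wildcard)
and (b) any from-state that has its own specific row for that target,
which overrides the wildcard. Event states are plain persistent states:
a member who has an infarction moves to the MI state and accrues its
cost and utility each subsequent year (states are mutually exclusive, so
the event replaces the prior state). No tunnel states are modeled.

### The stay probability and inconsistent inputs

Each row's diagonal is the residual `1 − (sum of exits + qx)`. If exits
exceed 1 the deterministic engine raises an error naming the state and
age — silent renormalization would hide inconsistent inputs. During
probabilistic sampling, where rare extreme draws are expected, the row
is instead proportionally rescaled to total exits of 0.999 and the event
is counted and reported, keeping the iteration count fixed.

## Parameters

* **states.csv** — per-state annual cost (USD/year, taken as already
  inflation-adjusted; the package does no CPI work), utility weight,
  cost and utility distribution specs, and a `reversible` flag. Exactly
  one state must be the healthy reference (cost 0, utility 1).
* **transitions.csv** — directed annual probabilities (stored as
  fractions: 0.0246 = 2.46%/year) with beta specs and a derivation flag
  (`literature`, `derived`, `calibrated`, `age_specific`). Exactly one
  row, `ANY -> DEATH`, is age-specific and carries no fixed probability.
* **lifetable.csv** — `age, qx`. The packaged file is a **synthetic**
  stand-in: a smooth Gompertz-type curve
  `qx = 0.0004 + 6.67e-5·exp(0.085·age)` over ages 0–100, anchored near
  published adult-US magnitudes (qx ≈ 0.0024 at 40, ≈ 0.06 at 80).
  Substitute a real national life table for production analyses.
* **scenario.yaml** — starting age (default 40), horizon (5 years),
  discount rate (0.03/year for both costs and QALYs), population
  (4,461), baseline state distribution, program cost (default $720 per
  member-year), intervention RRR map, remission map, savings split, and
  PSA settings. Unknown keys are rejected so typos cannot silently fall
  back to defaults.

Defaults that the underlying evidence base does not pin down — the
baseline state mix (beyond a 23.5% hypertension prevalence) and the
intervention effect sizes — are marked ILLUSTRATIVE in the scenario file
itself and echoed to stderr at run time, so their output cannot
masquerade as a literature-parameterized result.

### Published distribution parameters and rescaling

Gamma cost specs are interpreted as (shape, scale), which makes every
packaged row mean-consistent (shape × scale = the stated cost, e.g.
Gamma(100, 95) ↔ $9,500); a scale of 0 is degenerate at 0 and never
sampled. Published beta parameters for transition probabilities,
however, frequently imply means different from the stated point
estimates (e.g. Beta(50, 950) has mean 0.05, not 0.0246). The package
resolves this as follows: **deterministic runs always use the point
estimate**, and **probabilistic runs sample from
`rescale_beta_to_mean(point, α+β)`** — a beta with mean exactly the
point estimate and the published effective sample size α+β retained as
the spread signal. Mean-consistent rows (most utilities) are reproduced
verbatim by this rule, so it is a no-op where the inputs agree.

The healthy reference utility is fixed at 1 and never sampled (its
published spec is carried in the CSV but non-sampled): sampling the
reference above or below 1 would break the QALY anchor that all other
utilities are measured against.

The packaged "combined state → higher-risk" edges, published only as a
0.03–0.05% calibrated range, default to the midpoint 0.04%
(Beta(0.4, 999.6), effective n 1000 like neighbouring rows) and can be
overridden per-edge in the CSV.

## Economics

Treated per-member cost includes the discounted program cost, so the
per-member saving is net of the program; population net savings equal
per-member saving × population, and ROI divides net savings by program
costs. Because the published total program cost is not reconcilable
with `rate × years × members`, a `program_cost_total_override` lets the
user pin total program costs verbatim; it then replaces the accrued
figure in both the treated per-member cost and the ROI denominator.

The medication vs healthcare-services decomposition of gross medical
savings is presentational: a single `medication_fraction` (default
0.30, illustrative) allocates the gross figure, services savings are
computed as the exact complement so the decomposition always closes,
and the ROI depends only on the total. Internal computation is at full
precision; the report table rounds USD to whole dollars and — matching
the common reporting convention — differences the rounded per-arm
figures. The package reports ROI and savings, not cost-per-QALY: no
ICER machinery is included.

## Sensitivity analysis

**PSA.** Each iteration draws one joint parameter set (all parameters
independent: no correlation structure is asserted by the evidence base),
runs both arms, and records ROI and incremental QALYs; the summary
reports the mean and an empirical percentile interval (default
2.5/97.5, no normal approximation). Relative-risk multipliers are
sampled lognormally with **median equal to the base multiplier**
(sdlog `rrr_sigma`, default 0.1, settable to 0 to freeze them):
median-preservation keeps the deterministic run the central scenario.
Draws are capped at 1 so a sampled "effect" never becomes harmful,
which is the package's reading of a relative *reduction*.

All randomness flows from one top-level seed through named substreams
(`psa`, `synthetic`) with per-iteration derived seeds, so (a) reruns are
bit-identical, (b) extending `n_iter` leaves earlier iterations
unchanged, and (c) adding a new consumer of randomness never perturbs
existing streams.

**Tornado.** One parameter at a time is set to its low and high bound
(program cost, discount rate, any state cost or utility, any transition
probability, any RRR), the deterministic model is re-run, and results
are sorted by ROI swing.

## What the synthetic scenario generator does and does not emulate

`generate_synthetic_scenario()` emits a complete runnable scenario
directory (tables + YAML) with a requested baseline prevalence placed in
named states and the remainder healthy. It emulates the *structure* of a
real employer population — a mixed starting distribution over disease
states with a known hypertension prevalence — but not its correlation
with age, sex or BMI, nor claims-level cost variance, nor engagement
heterogeneity; members within a state are exchangeable. Tests passing on
generated scenarios therefore validate the bookkeeping (conservation,
discounting, arm accounting, determinism), not the external realism of
any particular parameterization.

## Test problem sizes

The suite exercises conservation on 1,000 randomly generated valid
models (3–6 states, horizons 1–10), the matrix-power oracle on 100
age-constant models at 1e−10, distribution sampling at 100,000 draws
against 3-standard-error bands, PSA determinism at 1,000 iterations and
convergence at 1,000 vs 2,000 iterations — sizes chosen so the full
suite runs in about a minute while keeping Monte-Carlo error well below
the asserted tolerances. Production PSA defaults to 10,000 iterations.

## Known limitations

* The control arm is a modeled comparator, not an observed cohort: all
  savings and QALY gains are conditional on the transition and cost
  assumptions.
* No lifetime-horizon extrapolation beyond the supplied life table, and
  no per-state pharmacy/medical cost split (the savings decomposition is
  a reporting fraction).
* Cancers, respiratory illness and mental-health conditions are not
  parameterized in the packaged tables; users can extend states.csv and
  transitions.csv, and validation will hold the extended tables to the
  same invariants.
* Engagement tiers are carried as a label on a scenario, not as a
  quantitative mechanism; model engagement by supplying tier-specific
  RRR/remission values.
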