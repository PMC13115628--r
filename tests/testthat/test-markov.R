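# Markov engine: discounting, matrix assembly, cohort propagation.

test_that("discount factor follows 1/(1+r)^t", {
  expect_equal(discount_factor(0.03, 0), 1.0)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(discount_factor(0, 0:7), rep(1, 8))
  expect_equal(discount_factor(0.05, 0:3), 1 / 1.05^(0:3))
  expect_error(discount_factor(0.03, -1), "nonnegative")
  expect_error(discount_factor(-0.01, 1), ">= 0")
})

test_that("default-model Healthy row reproduces the published exits", {
  st <- lbc_default_states()
  tt <- lbc_default_transitions()
  lt <- flat_life_table(qx = 0.002)
  M <- build_matrix(st, tt, lt, age = 40)
  # oracle: 1 - (sum of the published Healthy-applicable exits + q)
  exits <- 0.0246 + 0.0224 + 0.0037 + 0.0016 + 0.0010 + 0.0026 + 0.0020
  expect_equal(M["Healthy", "Healthy"], 1 - exits - 0.002)
  expect_equal(M["Healthy", "Healthy"], 0.9401)
  expect_equal(M["Healthy", "DEATH"], 0.002)
  # wildcard event rows reach every alive state, overrides intact
  expect_equal(M["HTN2", "MI"], 0.0010)
  expect_equal(M["MI", "MI"] >= 0.9, TRUE)   # no self-loop from ANY->MI
  expect_equal(M["DEATH", "DEATH"], 1)
  expect_true(all(abs(rowSums(M) - 1) < 1e-12))
  expect_true(all(M >= 0))
})

test_that("arm adjustments scale named edges multiplicatively", {
  st <- lbc_default_states()
  tt <- lbc_default_transitions()
  lt <- flat_life_table(qx = 0.002)
  M0 <- build_matrix(st, tt, lt, 40)
  M1 <- build_matrix(st, tt, lt, 40,
                     arm_adjustments = list("PreDM->DM" = 0.5))
  expect_equal(M0["PreDM", "DM"], 0.0112)
  expect_equal(M1["PreDM", "DM"], 0.0056)
  expect_equal(M1["PreDM", "PreDM"] - M0["PreDM", "PreDM"], 0.0056)
  # an ANY-keyed adjustment scales every expansion of that row
  M2 <- build_matrix(st, tt, lt, 40,
                     arm_adjustments = list("ANY->MI" = 0.5))
  expect_equal(M2["Healthy", "MI"], 0.0005)
  expect_equal(M2["HTN", "MI"], 0.0005)
})

test_that("death-only transitions give identity among alive states", {
  st <- tiny_states()
  tt <- death_only_transitions()
  lt <- flat_life_table(qx = 0.01)
  M <- build_matrix(st, tt, lt, 45)
  expect_equal(M["Healthy", "Healthy"], 0.99)
  expect_equal(M["Sick", "Sick"], 0.99)
  expect_equal(unname(M[c("Healthy", "Sick"), "DEATH"]), c(0.01, 0.01))
  expect_equal(M["Healthy", "Sick"], 0)
})

test_that("exit overflow errors name the state and age", {
  st <- tiny_states()
  tt <- tiny_transitions(p = 0.995)
  lt <- flat_life_table(qx = 0.1)
  expect_error(build_matrix(st, tt, lt, 42), "Healthy.*42")
  M <- build_matrix(st, tt, lt, 42, overflow = "rescale")
  expect_equal(sum(M["Healthy", c("Sick", "DEATH")]), 0.999)
  expect_equal(attr(M, "overflow_rescaled"), 1L)
  expect_true(all(abs(rowSums(M) - 1) < 1e-12))
})

test_that("an immortal healthy cohort accrues the closed-form QALYs", {
  st <- tiny_states()
  tt <- death_only_transitions()
  lt <- flat_life_table(qx = 0)
  cfg <- tiny_config()
  tr <- run_cohort(cfg, st, tt, lt, arm = "control")
  expect_equal(tr$total_qaly_disc, 5.0)
  expect_equal(tr$total_cost_disc, 0)
  cfg3 <- tiny_config(discount_rate = 0.03)
  tr3 <- run_cohort(cfg3, st, tt, lt, arm = "control")
  expect_equal(tr3$total_qaly_disc, sum(1 / 1.03^(0:4)))  # 4.717098...
  expect_equal(tr3$total_qaly_und, 5.0)
})

test_that("a single diseased state accrues its cost and utility", {
  st <- tiny_states(cost = 1200, utility = 0.88)
  tt <- death_only_transitions()
  lt <- flat_life_table(qx = 0)
  cfg <- scenario_config(baseline_distribution = list(Sick = 1), horizon = 1,
                         discount_rate = 0, program_cost_per_member_year = 0,
                         population = 100)
  tr <- run_cohort(cfg, st, tt, lt, arm = "control")
  expect_equal(tr$total_cost_disc, 1200)
  expect_equal(tr$total_qaly_disc, 0.88)
})

test_that("program cost accrues per alive member-year, discounted, treated arm only", {
  st <- tiny_states()
  tt <- death_only_transitions()
  lt <- flat_life_table(qx = 0.1)
  cfg <- scenario_config(baseline_distribution = list(Healthy = 1),
                         horizon = 3, discount_rate = 0.03,
                         program_cost_per_member_year = 720, population = 10)
  ctrl <- run_cohort(cfg, st, tt, lt, arm = "control")
  trt <- run_cohort(cfg, st, tt, lt, arm = "intervention")
  expect_equal(ctrl$total_program_disc, 0)
  alive <- 0.9^(0:2)
  expect_equal(trt$total_program_disc, sum(720 * alive / 1.03^(0:2)))
  expect_equal(trt$total_qaly_disc, ctrl$total_qaly_disc)
})

test_that("occupancy is conserved across cycles for random valid models", {
  for (seed in 1:25) {
    m <- random_model(seed)
    tr <- run_cohort(m$config, m$states, m$transitions, m$life_table,
                     arm = "control")
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9), info = seed)
    expect_true(all(tr$cycle_cost_disc >= 0), info = seed)
    expect_lte(tr$total_qaly_disc, tr$total_qaly_und + 1e-12)
    expect_lte(tr$total_qaly_und, m$config$horizon + 1e-12)
  }
})

test_that("cycle iteration agrees with the matrix-power oracle", {
  for (seed in 26:35) {
    m <- random_model(seed)
    m$life_table$qx[] <- m$life_table$qx[1]   # age-constant mortality
    tr <- run_cohort(m$config, m$states, m$transitions, m$life_table,
                     arm = "control")
    M <- build_matrix(m$states, m$transitions, m$life_table,
                      m$config$start_age)
    occ0 <- tr$occupancy[1, ]
    for (t in seq_len(m$config$horizon)) {
      expected <- as.numeric(occ0 %*% mat_power(unclass(M), t))
      expect_equal(as.numeric(tr$occupancy[t + 1, ]), expected,
                   tolerance = 1e-10, info = paste(seed, t))
    }
  }
})

test_that("raising a cost or the discount rate moves totals monotonically", {
  m <- random_model(101)
  base <- run_cohort(m$config, m$states, m$transitions, m$life_table,
                     arm = "control")
  st2 <- m$states
  st2$annual_cost[2] <- st2$annual_cost[2] + 5000
  up <- run_cohort(m$config, st2, m$transitions, m$life_table,
                   arm = "control")
  expect_gte(up$total_cost_disc, base$total_cost_disc)
  cfg2 <- m$config
  cfg2$discount_rate <- m$config$discount_rate + 0.05
  disc <- run_cohort(cfg2, m$states, m$transitions, m$life_table,
                     arm = "control")
  expect_lte(disc$total_qaly_disc, base$total_qaly_disc)
})

test_that("risk reduction with zero program cost never loses QALYs", {
  st <- lbc_default_states()
  tt <- lbc_default_transitions()
  lt <- lbc_default_life_table()
  rrr <- as.list(setNames(
    rep(0.5, 15),
    c("Healthy->Obesity", "Healthy->PreDM", "Healthy->PreHTN",
      "Obesity->PreDM", "Obesity->DM", "PreDM->DM", "PreDM->HighRiskDM",
      "PreHTN->HTN", "HTN->HTN2", "DM->HighRiskDM", "DM_HTN->HighRiskDM",
      "ANY->CAD", "ANY->MI", "ANY->CHF", "ANY->Stroke")))
  cfg <- scenario_config(
    baseline_distribution = list(Healthy = 0.5, Obesity = 0.3, DM = 0.2),
    program_cost_per_member_year = 0, intervention_rrr = rrr)
  ctrl <- run_cohort(cfg, st, tt, lt, arm = "control")
  trt <- run_cohort(cfg, st, tt, lt, arm = "intervention")
  expect_gte(trt$total_qaly_disc, ctrl$total_qaly_disc)
  expect_lte(trt$total_cost_disc, ctrl$total_cost_disc)
})

test_that("half-cycle correction averages start and end occupancy", {
  st <- tiny_states(cost = 1000, utility = 0.5)
  tt <- death_only_transitions()
  lt <- flat_life_table(qx = 0.5)
  cfg <- scenario_config(baseline_distribution = list(Sick = 1), horizon = 1,
                         discount_rate = 0, program_cost_per_member_year = 0,
                         population = 1, half_cycle_correction = TRUE)
  tr <- run_cohort(cfg, st, tt, lt, arm = "control")
  expect_equal(tr$total_cost_disc, 1000 * 0.75)  # mean of 1 and 0.5 alive
  expect_equal(tr$total_qaly_disc, 0.5 * 0.75)
})

test_that("baseline naming an unknown state is rejected", {
  st <- tiny_states()
  tt <- death_only_transitions()
  lt <- flat_life_table()
  cfg <- tiny_config()
  cfg$baseline_distribution <- list(Ghost = 1)
  expect_error(run_cohort(cfg, st, tt, lt, arm = "control"), "Ghost")
})

test_that("remission edges apply to the intervention arm only", {
  st <- tiny_states(reversible = TRUE)
  tt <- tiny_transitions(p = 0.2)
  lt <- flat_life_table(qx = 0)
  cfg <- scenario_config(baseline_distribution = list(Sick = 1), horizon = 2,
                         discount_rate = 0, program_cost_per_member_year = 0,
                         population = 1,
                         remission_probs = list("Sick->Healthy" = 0.3))
  ctrl <- run_cohort(cfg, st, tt, lt, arm = "control")
  trt <- run_cohort(cfg, st, tt, lt, arm = "intervention")
  expect_equal(ctrl$occupancy[2, "Healthy"], 0)
  expect_equal(trt$occupancy[2, "Healthy"], 0.3)
  expect_gt(trt$total_qaly_disc, ctrl$total_qaly_disc)
  # remission out of a non-reversible state is rejected
  cfg_bad <- cfg
  expect_error(
    run_cohort(cfg_bad, tiny_states(reversible = FALSE), tt, lt,
               arm = "intervention"),
    "not marked reversible")
})
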