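# Fixtures built in code: tiny hand-sized models plus a generator of
# random valid parameter sets for property-style tests.

flat_life_table <- function(qx = 0.002, ages = 40:60) {
  validate_life_table(data.frame(age = ages, qx = qx))
}

# Two-state model: one reference state and one diseased state.
tiny_states <- function(cost = 1200, utility = 0.88, reversible = FALSE) {
  validate_state_table(data.frame(
    state_id = c("Healthy", "Sick"), label = c("Healthy", "Sick"),
    annual_cost = c(0, cost), utility = c(1, utility),
    cost_dist_family = c("gamma", "gamma"), cost_a = c(100, 100),
    cost_b = c(0, cost / 100),
    utility_dist_family = c("fixed", "beta"), utility_a = c(1, utility * 100),
    utility_b = c(NA, (1 - utility) * 100),
    reversible = c(FALSE, reversible), stringsAsFactors = FALSE))
}

tiny_transitions <- function(p = 0.1) {
  validate_transition_table(data.frame(
    from_state = c("Healthy", "ANY"), to_state = c("Sick", "DEATH"),
    annual_prob = c(p, NA), dist_family = c("beta", "beta"),
    dist_a = c(p * 1000, NA), dist_b = c((1 - p) * 1000, NA),
    derivation_flag = c("literature", "age_specific"),
    stringsAsFactors = FALSE))
}

# Transition table containing only the mandatory age-specific death row.
death_only_transitions <- function() {
  validate_transition_table(data.frame(
    from_state = "ANY", to_state = "DEATH", annual_prob = NA,
    dist_family = "beta", dist_a = NA, dist_b = NA,
    derivation_flag = "age_specific", stringsAsFactors = FALSE))
}

tiny_config <- function(discount_rate = 0, ...) {
  scenario_config(baseline_distribution = list(Healthy = 1), horizon = 5,
                  discount_rate = discount_rate,
                  program_cost_per_member_year = 0, population = 100, ...)
}

# Random valid model: 3-6 alive states, sparse transitions with small
# probabilities, random flat-ish life table.  Deterministic given seed.
random_model <- function(seed) {
  set.seed(seed)
  n <- sample(3:6, 1)
  ids <- c("Ref", paste0("S", seq_len(n - 1)))
  cost <- c(0, round(runif(n - 1, 500, 20000)))
  util <- c(1, round(runif(n - 1, 0.3, 0.95), 3))
  states <- validate_state_table(data.frame(
    state_id = ids, label = ids, annual_cost = cost, utility = util,
    cost_dist_family = "gamma", cost_a = 100, cost_b = cost / 100,
    utility_dist_family = c("fixed", rep("beta", n - 1)),
    utility_a = c(1, util[-1] * 200),
    utility_b = c(NA, (1 - util[-1]) * 200),
    reversible = FALSE, stringsAsFactors = FALSE))
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
  probs <- runif(nrow(pairs), 0.001, 0.5 / n)
  k <- nrow(pairs)
  tdf <- data.frame(from_state = pairs$from, to_state = pairs$to,
                    annual_prob = probs, dist_family = rep("beta", k),
                    dist_a = probs * 500, dist_b = (1 - probs) * 500,
                    derivation_flag = rep("literature", k),
                    stringsAsFactors = FALSE)
  if (runif(1) < 0.5) {
    p_any <- runif(1, 0.001, 0.02)
    tdf <- rbind(tdf, data.frame(from_state = "ANY", to_state = ids[n],
                                 annual_prob = p_any, dist_family = "beta",
                                 dist_a = p_any * 500,
                                 dist_b = (1 - p_any) * 500,
                                 derivation_flag = "literature",
                                 stringsAsFactors = FALSE))
  }
  tdf <- rbind(tdf, data.frame(from_state = "ANY", to_state = "DEATH",
                               annual_prob = NA, dist_family = "beta",
                               dist_a = NA, dist_b = NA,
                               derivation_flag = "age_specific",
                               stringsAsFactors = FALSE))
  transitions <- validate_transition_table(tdf, states = states)
  life_table <- validate_life_table(
    data.frame(age = 40:60, qx = round(runif(21, 0.001, 0.05), 5)))
  w <- runif(n); w <- w / sum(w)
  config <- scenario_config(
    start_age = 40, horizon = sample(1:10, 1),
    discount_rate = runif(1, 0, 0.06), population = 1000,
    baseline_distribution = as.list(setNames(w, ids)),
    program_cost_per_member_year = runif(1, 0, 1000))
  list(states = states, transitions = transitions, life_table = life_table,
       config = config)
}

# Independent oracle: matrix power by repeated multiplication.
mat_power <- function(M, k) {
  out <- diag(nrow(M))
  dimnames(out) <- dimnames(M)
  for (i in seq_len(k)) out <- out %*% M
  out
}

write_tmp_csv <- function(df, dir = tempdir()) {
  path <- tempfile(fileext = ".csv", tmpdir = dir)
  write.csv(df, path, row.names = FALSE)
  path
}
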