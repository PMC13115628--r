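SCENARIO_KEYS <- c("start_age", "horizon", "discount_rate", "population",
                   "baseline_distribution", "program_cost_per_member_year",
                   "program_cost_total_override", "intervention_rrr",
                   "remission_probs", "engagement_tier", "savings_split",
                   "half_cycle_correction", "psa",
                   "states_file", "transitions_file", "lifetable_file")
PSA_KEYS <- c("n_iter", "seed", "percentiles", "rrr_sigma")
SPLIT_KEYS <- c("medication_fraction")

#' Construct a scenario configuration
#'
#' The scenario gathers every adjustable input of the tool: cohort
#' (starting age, size, baseline state distribution), analysis settings
#' (time horizon, discount rate), program cost, the intervention's effect
#' (relative-risk multipliers on progression/incidence edges and optional
#' remission probabilities out of reversible states), and probabilistic
#' sensitivity analysis settings.
#'
#' @param start_age Starting age of the cohort in years (default 40).
#' @param horizon Time horizon in annual cycles (default 5).
#' @param discount_rate Annual discount rate applied to both costs and
#'   QALYs (default 0.03).
#' @param population Number of members the per-member expectations are
#'   scaled to (default 4461).
#' @param baseline_distribution Named list/vector mapping `state_id` to the
#'   fraction of the cohort starting in that state; must sum to 1.
#' @param program_cost_per_member_year Program cost in USD per alive
#'   member-year, intervention arm only (default 720).
#' @param program_cost_total_override Optional total population program
#'   cost in USD; when set it is used verbatim for the savings
#'   decomposition and ROI in place of the accrued per-member-year cost.
#' @param intervention_rrr Named list mapping transition edges
#'   (`"From->To"`, or `"ANY->To"` for wildcard rows) to relative-risk
#'   multipliers in (0, 1\] applied in the intervention arm.
#' @param remission_probs Named list mapping `"From->To"` edges out of
#'   reversible states to annual improvement probabilities added in the
#'   intervention arm (default none).
#' @param engagement_tier Free-text label attached to this rrr/remission
#'   set (e.g. coaching intensity); not used numerically.
#' @param savings_split List with `medication_fraction` in \[0, 1\]: the
#'   share of gross medical savings reported as medication savings (the
#'   remainder is healthcare-services savings).
#' @param half_cycle_correction Logical; accrue costs/QALYs on the average
#'   of start- and end-of-cycle occupancy instead of start-of-cycle
#'   (default `FALSE`).
#' @param psa List with `n_iter` (default 10000), `seed`, `percentiles`
#'   (default `c(0.025, 0.975)`) and `rrr_sigma`, the lognormal sdlog used
#'   to sample relative-risk multipliers (default 0.1).
#' @param states_file,transitions_file,lifetable_file Optional paths to
#'   input tables; packaged defaults are used when absent.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(start_age = 40, horizon = 5, discount_rate = 0.03,
                            population = 4461,
                            baseline_distribution = list(Healthy = 1),
                            program_cost_per_member_year = 720,
                            program_cost_total_override = NULL,
                            intervention_rrr = list(),
                            remission_probs = list(),
                            engagement_tier = NULL,
                            savings_split = list(medication_fraction = 0.30),
                            half_cycle_correction = FALSE,
                            psa = list(),
                            states_file = NULL, transitions_file = NULL,
                            lifetable_file = NULL) {
  psa_full <- utils::modifyList(
    list(n_iter = 10000L, seed = 1L, percentiles = c(0.025, 0.975),
         rrr_sigma = 0.1),
    psa)
  cfg <- list(start_age = start_age, horizon = horizon,
              discount_rate = discount_rate, population = population,
              baseline_distribution = as.list(baseline_distribution),
              program_cost_per_member_year = program_cost_per_member_year,
              program_cost_total_override = program_cost_total_override,
              intervention_rrr = as.list(intervention_rrr),
              remission_probs = as.list(remission_probs),
              engagement_tier = engagement_tier,
              savings_split = savings_split,
              half_cycle_correction = isTRUE(half_cycle_correction),
              psa = psa_full,
              states_file = states_file, transitions_file = transitions_file,
              lifetable_file = lifetable_file)
  validate_scenario(cfg)
}

#' Read a scenario configuration from YAML
#'
#' Unknown keys are rejected outright, so a typo in a parameter name can
#' never silently fall back to a default.
#'
#' @param path Path to a YAML (or JSON) scenario file.
#' @return A validated `scenario_config`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), SCENARIO_KEYS)
  if (length(unknown))
    stop("scenario config: unknown key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(SCENARIO_KEYS, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$psa)) {
    unknown <- setdiff(names(raw$psa), PSA_KEYS)
    if (length(unknown))
      stop("scenario config: unknown psa key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (!is.null(raw$psa$percentiles))
      raw$psa$percentiles <- as.numeric(unlist(raw$psa$percentiles))
  }
  if (!is.null(raw$savings_split)) {
    unknown <- setdiff(names(raw$savings_split), SPLIT_KEYS)
    if (length(unknown))
      stop("scenario config: unknown savings_split key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- do.call(scenario_config, raw)
  cfg$config_dir <- dirname(normalizePath(path))
  cfg
}

#' Validate a scenario configuration
#'
#' @param cfg A list with `scenario_config` fields.
#' @param states,transitions Optional tables; when supplied, the baseline
#'   distribution, rrr keys and remission keys are resolved against them.
#' @return `cfg`, classed as `scenario_config`.
#' @export
validate_scenario <- function(cfg, states = NULL, transitions = NULL) {
  fail <- function(field, msg)
    stop(sprintf("scenario config, field '%s': %s", field, msg), call. = FALSE)
  if (!is.numeric(cfg$start_age) || cfg$start_age < 0)
    fail("start_age", "must be a nonnegative number of years")
  if (!is.numeric(cfg$horizon) || cfg$horizon < 1 ||
      cfg$horizon != round(cfg$horizon))
    fail("horizon", "must be a whole number of years >= 1")
  if (!is.numeric(cfg$discount_rate) || cfg$discount_rate < 0)
    fail("discount_rate", "must be >= 0")
  if (!is.numeric(cfg$population) || cfg$population <= 0)
    fail("population", "must be > 0")
  bd <- unlist(cfg$baseline_distribution)
  if (is.null(names(bd)) || any(names(bd) == ""))
    fail("baseline_distribution", "must be a named state_id -> fraction map")
  if (any(bd < 0)) fail("baseline_distribution", "fractions must be >= 0")
  if (abs(sum(bd) - 1) > 1e-9)
    fail("baseline_distribution",
         sprintf("fractions must sum to 1 (got %.12f)", sum(bd)))
  if (!is.numeric(cfg$program_cost_per_member_year) ||
      cfg$program_cost_per_member_year < 0)
    fail("program_cost_per_member_year", "must be >= 0")
  if (!is.null(cfg$program_cost_total_override) &&
      (!is.numeric(cfg$program_cost_total_override) ||
       cfg$program_cost_total_override < 0))
    fail("program_cost_total_override", "must be >= 0 when set")
  rrr <- unlist(cfg$intervention_rrr)
  if (length(rrr) && (any(rrr <= 0) || any(rrr > 1)))
    fail("intervention_rrr", "multipliers must lie in (0, 1]")
  rem <- unlist(cfg$remission_probs)
  if (length(rem) && (any(rem < 0) || any(rem >= 1)))
    fail("remission_probs", "probabilities must lie in [0, 1)")
  mf <- cfg$savings_split$medication_fraction
  if (!is.numeric(mf) || mf < 0 || mf > 1)
    fail("savings_split.medication_fraction", "must lie in [0, 1]")
  p <- cfg$psa
  if (!is.numeric(p$n_iter) || p$n_iter < 1 || p$n_iter != round(p$n_iter))
    fail("psa.n_iter", "must be a whole number >= 1")
  if (length(p$percentiles) != 2 || any(p$percentiles <= 0) ||
      any(p$percentiles >= 1) || p$percentiles[1] >= p$percentiles[2])
    fail("psa.percentiles", "must be two ascending fractions in (0, 1)")
  if (!is.numeric(p$rrr_sigma) || p$rrr_sigma < 0)
    fail("psa.rrr_sigma", "must be >= 0 (0 keeps multipliers fixed)")

  if (!is.null(states)) {
    unknown <- setdiff(names(bd), states$state_id)
    if (length(unknown))
      fail("baseline_distribution",
           paste("unknown state(s):", paste(unknown, collapse = ", ")))
    if (!is.null(transitions)) {
      edge_keys <- c(paste(transitions$from_state, transitions$to_state,
                           sep = "->"),
                     with(expand_edges(states, transitions),
                          paste(from_state, to_state, sep = "->")))
      unknown <- setdiff(names(cfg$intervention_rrr), edge_keys)
      if (length(unknown))
        fail("intervention_rrr",
             paste("key(s) name no existing transition edge:",
                   paste(unknown, collapse = ", ")))
    }
    for (k in names(cfg$remission_probs)) {
      ft <- parse_edge_key(k)
      if (!ft[1] %in% states$state_id || !ft[2] %in% states$state_id)
        fail("remission_probs", paste("unknown state in edge", k))
      if (!states$reversible[states$state_id == ft[1]])
        fail("remission_probs",
             paste0("state '", ft[1], "' is not marked reversible"))
    }
  }
  structure(cfg, class = "scenario_config")
}

# "From->To" (whitespace-tolerant) -> c(from, to)
parse_edge_key <- function(key) {
  parts <- strsplit(key, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("edge key must have the form 'From->To': ", key, call. = FALSE)
  trimws(parts)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario: start age", x$start_age, "| horizon", x$horizon,
      "y | discount", x$discount_rate, "| population", x$population, "\n")
  cat("Program cost:", x$program_cost_per_member_year, "USD/member-year",
      if (!is.null(x$program_cost_total_override))
        sprintf("(total override %s)",
                format(x$program_cost_total_override, big.mark = ",")),
      "\n")
  bd <- unlist(x$baseline_distribution)
  cat("Baseline:", paste(sprintf("%s=%.3g", names(bd), bd), collapse = ", "),
      "\n")
  cat("Intervention edges with rrr:", length(x$intervention_rrr),
      "| remission edges:", length(x$remission_probs), "\n")
  invisible(x)
}
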