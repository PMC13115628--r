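#' Discount factor
#'
#' Standard annual discounting: a cost or QALY accrued in cycle `t` is
#' weighted by `1 / (1 + rate)^t`, with cycle 0 undiscounted.
#'
#' @param rate Annual discount rate as a fraction (>= 0).
#' @param cycle Integer cycle index (>= 0); vectorized.
#' @return `1 / (1 + rate)^cycle`.
#' @examples
#' discount_factor(0.03, 0:4)
#' @export
discount_factor <- function(rate, cycle) {
  if (!is.numeric(rate) || rate < 0) stop("rate must be >= 0", call. = FALSE)
  if (any(cycle < 0) || any(cycle != round(cycle)))
    stop("cycle must be a nonnegative integer", call. = FALSE)
  1 / (1 + rate)^cycle
}

#' Build the annual transition matrix at a given age
#'
#' Assembles the square row-stochastic matrix over the alive states plus
#' the absorbing `DEATH` state: wildcard `ANY ->` rows are expanded to
#' every alive from-state lacking a specific override, the `DEATH` column
#' is filled with the life-table mortality `qx` at `age`, any arm
#' adjustments (relative-risk multipliers, added remission edges) are
#' applied, and the diagonal is set to one minus the row's total exit
#' probability.
#'
#' @param states A `state_table`.
#' @param transitions A `transition_table`.
#' @param life_table A `life_table`.
#' @param age Age in whole years the matrix applies to.
#' @param arm_adjustments Optional named list of multipliers keyed by edge
#'   (`"From->To"`); a key may name either a concrete expanded edge or the
#'   wildcard row (`"ANY->To"`), in which case it scales every expansion of
#'   that row.  Concrete keys take precedence.
#' @param extra_edges Optional named list of additional annual exit
#'   probabilities keyed by `"From->To"` (used for intervention-arm
#'   remission edges); added to the row before the stay probability is
#'   computed.
#' @param overflow `"error"` (default): a row whose exits (including
#'   mortality) exceed 1 is an error naming the state and age.
#'   `"rescale"`: such a row has all its exits proportionally rescaled to
#'   a total of 0.999, and the event count is recorded in attribute
#'   `overflow_rescaled` (used during probabilistic sampling).
#' @return A matrix of class `transition_matrix` with dimnames
#'   `c(state_id..., "DEATH")`, rows summing to 1, and attribute `age`.
#' @export
build_matrix <- function(states, transitions, life_table, age,
                         arm_adjustments = NULL, extra_edges = NULL,
                         overflow = c("error", "rescale")) {
  overflow <- match.arg(overflow)
  flow <- alive_exit_flows(states, transitions, arm_adjustments, extra_edges)
  assemble_matrix(flow, q = mortality_at(life_table, age), age = age,
                  overflow = overflow)
}

# Age-independent alive-to-alive exit flows (off-diagonal probabilities),
# with arm adjustments and extra (remission) edges applied.  Computed once
# per cohort run; mortality and the diagonal are filled in per age.
alive_exit_flows <- function(states, transitions, arm_adjustments = NULL,
                             extra_edges = NULL) {
  alive <- states$state_id
  n <- length(alive)
  F <- matrix(0, n, n, dimnames = list(alive, alive))
  edges <- expand_edges(states, transitions)
  if (nrow(edges)) {
    mult <- rep(1, nrow(edges))
    if (length(arm_adjustments)) {
      ckey <- paste(edges$from_state, edges$to_state, sep = "->")
      rkey <- ifelse(edges$wildcard,
                     paste(ANY_TOKEN, edges$to_state, sep = "->"), ckey)
      for (k in names(arm_adjustments)) {
        hit <- ckey == k
        if (!any(hit)) hit <- rkey == k
        mult[hit] <- mult[hit] * arm_adjustments[[k]]
      }
    }
    F[cbind(match(edges$from_state, alive), match(edges$to_state, alive))] <-
      F[cbind(match(edges$from_state, alive), match(edges$to_state, alive))] +
      edges$annual_prob * mult
  }
  for (k in names(extra_edges)) {
    ft <- parse_edge_key(k)
    if (!all(ft %in% alive))
      stop("extra edge names unknown state: ", k, call. = FALSE)
    F[ft[1], ft[2]] <- F[ft[1], ft[2]] + extra_edges[[k]]
  }
  F
}

# Compose the full row-stochastic matrix from alive flows and mortality q.
assemble_matrix <- function(flow, q, age, overflow = "error") {
  alive <- rownames(flow)
  all_states <- c(alive, DEATH_TOKEN)
  n <- length(all_states)
  M <- matrix(0, n, n, dimnames = list(all_states, all_states))
  M[alive, alive] <- flow
  M[alive, DEATH_TOKEN] <- q
  exits <- rowSums(M[alive, , drop = FALSE])
  over <- exits > 1
  rescued <- 0L
  if (any(over)) {
    if (overflow == "error")
      stop(sprintf(paste0("state '%s' at age %d: exit probabilities sum ",
                          "to %.6f > 1; inputs are inconsistent"),
                   alive[which(over)[1]], as.integer(age),
                   exits[which(over)[1]]), call. = FALSE)
    M[alive[over], ] <- M[alive[over], , drop = FALSE] * (0.999 / exits[over])
    exits[over] <- 0.999
    rescued <- sum(over)
  }
  diag(M)[seq_along(alive)] <- diag(M)[seq_along(alive)] + (1 - exits)
  M[DEATH_TOKEN, DEATH_TOKEN] <- 1
  structure(M, age = as.integer(age), overflow_rescaled = rescued,
            class = c("transition_matrix", "matrix", "array"))
}

#' Run the cohort simulation for one arm
#'
#' Propagates the cohort occupancy vector through annual cycles, accruing
#' per-member direct medical costs and QALYs (utility times time in
#' state), discounted per cycle.  The intervention arm applies the
#' scenario's relative-risk multipliers and remission edges and
#' additionally accrues the program cost per alive member-year.
#'
#' Accrual uses start-of-cycle occupancy by default; with
#' `config$half_cycle_correction` the average of start- and end-of-cycle
#' occupancy is used instead.
#'
#' @param config A `scenario_config`.
#' @param states A `state_table`.
#' @param transitions A `transition_table`.
#' @param life_table A `life_table`.
#' @param arm `"control"` or `"intervention"`.
#' @param overflow Passed to [build_matrix()].
#' @param validate Revalidate the scenario against the tables before
#'   running (default `TRUE`; the probabilistic loop disables it after
#'   validating once).
#' @return A `cohort_trace`: list with the occupancy matrix (`horizon + 1`
#'   rows, one per cycle boundary; columns alive states plus `DEATH`),
#'   per-cycle undiscounted/discounted per-member cost and QALY vectors,
#'   the per-cycle discounted medical and program components, and
#'   cumulative totals (`total_cost_disc`, `total_medical_disc`,
#'   `total_program_disc`, `total_qaly_disc`, and undiscounted
#'   counterparts).  All monetary amounts are USD per member.
#' @export
run_cohort <- function(config, states, transitions, life_table,
                       arm = c("control", "intervention"),
                       overflow = c("error", "rescale"), validate = TRUE) {
  arm <- match.arg(arm)
  overflow <- match.arg(overflow)
  if (validate)
    validate_scenario(config, states = states, transitions = transitions)
  alive <- states$state_id
  all_states <- c(alive, DEATH_TOKEN)
  h <- as.integer(config$horizon)

  bd <- unlist(config$baseline_distribution)
  unknown <- setdiff(names(bd), alive)
  if (length(unknown))
    stop("baseline_distribution names unparameterized state(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  occ <- stats::setNames(numeric(length(all_states)), all_states)
  occ[names(bd)] <- bd

  adjustments <- if (arm == "intervention") config$intervention_rrr else NULL
  extra <- if (arm == "intervention") config$remission_probs else NULL
  pc <- if (arm == "intervention") config$program_cost_per_member_year else 0

  cost_s <- stats::setNames(c(states$annual_cost, 0), all_states)
  util_s <- stats::setNames(c(states$utility, 0), all_states)

  occupancy <- matrix(0, h + 1, length(all_states),
                      dimnames = list(cycle = 0:h, state = all_states))
  occupancy[1, ] <- occ
  med_und <- qaly_und <- prog_und <- numeric(h)
  overflow_events <- 0L
  flows <- alive_exit_flows(states, transitions, adjustments, extra)
  for (t in seq_len(h) - 1L) {
    M <- assemble_matrix(flows,
                         q = mortality_at(life_table, config$start_age + t),
                         age = config$start_age + t, overflow = overflow)
    overflow_events <- overflow_events + attr(M, "overflow_rescaled")
    occ_next <- as.numeric(occ %*% M)
    names(occ_next) <- all_states
    occ_acc <- if (config$half_cycle_correction) (occ + occ_next) / 2 else occ
    med_und[t + 1] <- sum(occ_acc * cost_s)
    qaly_und[t + 1] <- sum(occ_acc * util_s)
    prog_und[t + 1] <- pc * sum(occ_acc[alive])
    occ <- occ_next
    occupancy[t + 2, ] <- occ
  }
  df <- discount_factor(config$discount_rate, seq_len(h) - 1L)
  trace <- list(
    arm = arm, horizon = h, start_age = config$start_age,
    discount_rate = config$discount_rate, population = config$population,
    occupancy = occupancy,
    cycle_medical_und = med_und, cycle_program_und = prog_und,
    cycle_cost_und = med_und + prog_und, cycle_qaly_und = qaly_und,
    cycle_medical_disc = med_und * df, cycle_program_disc = prog_und * df,
    cycle_cost_disc = (med_und + prog_und) * df, cycle_qaly_disc = qaly_und * df,
    overflow_events = overflow_events)
  trace$total_medical_und <- sum(trace$cycle_medical_und)
  trace$total_program_und <- sum(trace$cycle_program_und)
  trace$total_cost_und <- sum(trace$cycle_cost_und)
  trace$total_qaly_und <- sum(trace$cycle_qaly_und)
  trace$total_medical_disc <- sum(trace$cycle_medical_disc)
  trace$total_program_disc <- sum(trace$cycle_program_disc)
  trace$total_cost_disc <- sum(trace$cycle_cost_disc)
  trace$total_qaly_disc <- sum(trace$cycle_qaly_disc)
  structure(trace, class = "cohort_trace")
}

#' Construct a trace from aggregate totals
#'
#' Builds a minimal `cohort_trace` directly from aggregate per-member
#' results — e.g. externally computed or published totals — so the
#' economics layer can be applied to results that did not come from
#' [run_cohort()].
#'
#' @param arm `"control"` or `"intervention"`.
#' @param horizon Time horizon in years the totals cover.
#' @param total_cost Total discounted cost per member, USD (including any
#'   program cost).
#' @param total_qaly Total discounted QALYs per member.
#' @param program_cost Portion of `total_cost` that is program cost, USD
#'   (default 0); the remainder is direct medical cost.
#' @return A `cohort_trace` carrying only totals (no per-cycle detail).
#' @examples
#' treated <- cohort_trace_totals("intervention", 5, 41431, 4.7,
#'                                program_cost = 980)
#' @export
cohort_trace_totals <- function(arm = c("control", "intervention"), horizon,
                                total_cost, total_qaly, program_cost = 0) {
  arm <- match.arg(arm)
  if (total_cost < 0 || program_cost < 0 || program_cost > total_cost)
    stop("need 0 <= program_cost <= total_cost", call. = FALSE)
  structure(list(arm = arm, horizon = as.integer(horizon),
                 total_medical_disc = total_cost - program_cost,
                 total_program_disc = program_cost,
                 total_cost_disc = total_cost,
                 total_qaly_disc = total_qaly),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace (%s arm), horizon %d y\n", x$arm, x$horizon))
  cat(sprintf("  Discounted per member: cost $%s (medical $%s + program $%s), QALY %.4f\n",
              format(round(x$total_cost_disc, 2), big.mark = ","),
              format(round(x$total_medical_disc, 2), big.mark = ","),
              format(round(x$total_program_disc, 2), big.mark = ","),
              x$total_qaly_disc))
  if (!is.null(x$occupancy)) {
    alive_end <- 1 - x$occupancy[nrow(x$occupancy), DEATH_TOKEN]
    cat(sprintf("  Alive at end of horizon: %.2f%%\n", 100 * alive_end))
  }
  invisible(x)
}

#' Write a cohort trace to CSV
#'
#' One row per cycle per state (`cycle`, `state_id`, `occupancy`,
#' `disc_cost`, `disc_qaly`) followed by a `TOTAL` row.  Per-state
#' discounted cost and QALY apportion each accrual cycle's amounts by the
#' occupancy the accrual used; the final cycle boundary rows carry
#' occupancy only.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param path Output CSV path.
#' @param states The `state_table` the trace was run with.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, states) {
  if (is.null(trace$occupancy))
    stop("trace has no per-cycle detail (built from totals?)", call. = FALSE)
  all_states <- colnames(trace$occupancy)
  alive <- setdiff(all_states, DEATH_TOKEN)
  cost_s <- stats::setNames(c(states$annual_cost, 0), c(states$state_id, DEATH_TOKEN))
  util_s <- stats::setNames(c(states$utility, 0), c(states$state_id, DEATH_TOKEN))
  h <- trace$horizon
  dfac <- discount_factor(trace$discount_rate, 0:(h - 1))
  rows <- list()
  for (t in 0:h) {
    occ <- trace$occupancy[t + 1, ]
    if (t < h) {
      disc_cost <- occ * cost_s[all_states] * dfac[t + 1]
      # program cost is not state-specific; spread over alive occupancy
      if (trace$cycle_program_disc[t + 1] > 0) {
        alive_frac <- sum(occ[alive])
        if (alive_frac > 0)
          disc_cost[alive] <- disc_cost[alive] +
            trace$cycle_program_disc[t + 1] * occ[alive] / alive_frac
      }
      disc_qaly <- occ * util_s[all_states] * dfac[t + 1]
    } else {
      disc_cost <- disc_qaly <- rep(NA_real_, length(all_states))
    }
    rows[[t + 1]] <- data.frame(cycle = t, state_id = all_states,
                                occupancy = as.numeric(occ),
                                disc_cost = as.numeric(disc_cost),
                                disc_qaly = as.numeric(disc_qaly))
  }
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(cycle = NA, state_id = "TOTAL",
                               occupancy = NA,
                               disc_cost = trace$total_cost_disc,
                               disc_qaly = trace$total_qaly_disc))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
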