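#' @title Model parameter tables
#' @name parameter-tables
#' @description
#' Three plain-text tables parameterize the model:
#'
#' * the **state table** — one row per alive health state, with its annual
#'   direct medical cost (USD/year), utility weight (0–1), the uncertainty
#'   distributions of both, and a flag marking states that the intervention
#'   may improve (obesity, diabetes, hypertension by default);
#' * the **transition table** — directed annual transition probabilities
#'   between states, including `ANY ->` event rows that apply from every
#'   alive state and a single age-specific `ANY -> DEATH` row resolved from
#'   the life table at run time;
#' * the **life table** — age-indexed annual probabilities of death `qx`.
#'
#' Death is an implicit absorbing state (cost 0, utility 0) and never
#' appears in the state table.
NULL

ANY_TOKEN <- "ANY"
DEATH_TOKEN <- "DEATH"

STATE_CSV_COLS <- c("state_id", "label", "annual_cost_usd", "utility",
                    "cost_dist_family", "cost_a", "cost_b",
                    "utility_dist_family", "utility_a", "utility_b",
                    "reversible")
TRANS_CSV_COLS <- c("from_state", "to_state", "annual_prob",
                    "dist_family", "dist_a", "dist_b", "derivation_flag")
DERIVATION_FLAGS <- c("literature", "derived", "calibrated", "age_specific")

#' Read and validate a state table
#'
#' @param path Path to a CSV with columns
#'   `state_id,label,annual_cost_usd,utility,cost_dist_family,cost_a,cost_b,utility_dist_family,utility_a,utility_b,reversible`.
#' @return A `data.frame` of class `state_table` with columns `state_id`,
#'   `label`, `annual_cost` (USD/year), `utility`, the six distribution
#'   columns and logical `reversible`.
#' @details Validation enforces: unique `state_id`s; `annual_cost >= 0`;
#'   `utility` in \[0, 1\]; exactly one healthy reference state with cost 0
#'   and utility 1; no explicit death state; valid distribution parameters.
#' @seealso [lbc_default_states()] for the packaged default table.
#' @export
read_state_table <- function(path) {
  df <- read_checked_csv(path, STATE_CSV_COLS)
  names(df)[names(df) == "annual_cost_usd"] <- "annual_cost"
  df$state_id <- as.character(df$state_id)
  df$label <- as.character(df$label)
  df$reversible <- as.logical(df$reversible)
  validate_state_table(df)
}

#' Validate a state table
#'
#' @param df A data.frame with state-table columns (internal name
#'   `annual_cost`).
#' @return `df`, classed as `state_table`, invisibly checked.
#' @export
validate_state_table <- function(df) {
  row_err <- function(i, field, msg) {
    stop(sprintf("state table row %d (%s), field '%s': %s",
                 i, df$state_id[i], field, msg), call. = FALSE)
  }
  if (anyDuplicated(df$state_id))
    stop("state table: duplicate state_id: ",
         paste(unique(df$state_id[duplicated(df$state_id)]), collapse = ", "),
         call. = FALSE)
  if (any(toupper(df$state_id) %in% c(DEATH_TOKEN, ANY_TOKEN)))
    stop("state table: the death state is implicit and ANY is reserved; ",
         "neither may appear as a state_id", call. = FALSE)
  for (i in seq_len(nrow(df))) {
    if (!is.finite(df$annual_cost[i]) || df$annual_cost[i] < 0)
      row_err(i, "annual_cost_usd", "must be a number >= 0")
    if (!is.finite(df$utility[i]) || df$utility[i] < 0 || df$utility[i] > 1)
      row_err(i, "utility", sprintf("must lie in [0, 1], got %s", df$utility[i]))
    if (is.na(df$reversible[i]))
      row_err(i, "reversible", "must be TRUE or FALSE")
    validate_dist_params(match.arg(df$cost_dist_family[i],
                                   c("beta", "gamma", "lognormal", "fixed")),
                         df$cost_a[i], df$cost_b[i],
                         where = sprintf("state %s cost_dist", df$state_id[i]))
    validate_dist_params(match.arg(df$utility_dist_family[i],
                                   c("beta", "gamma", "lognormal", "fixed")),
                         df$utility_a[i], df$utility_b[i],
                         where = sprintf("state %s utility_dist", df$state_id[i]))
  }
  ref <- df$annual_cost == 0 & df$utility == 1
  if (sum(ref) != 1L)
    stop("state table: exactly one healthy reference state ",
         "(annual_cost 0, utility 1) is required; found ", sum(ref),
         call. = FALSE)
  structure(df, class = c("state_table", "data.frame"),
            reference_state = df$state_id[ref])
}

#' Write a state table to CSV
#'
#' Inverse of [read_state_table()]: numeric fields round-trip at full
#' precision.
#'
#' @param x A `state_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_state_table <- function(x, path) {
  out <- as.data.frame(x)
  names(out)[names(out) == "annual_cost"] <- "annual_cost_usd"
  utils::write.csv(out[, STATE_CSV_COLS], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Read and validate a transition table
#'
#' @param path Path to a CSV with columns
#'   `from_state,to_state,annual_prob,dist_family,dist_a,dist_b,derivation_flag`.
#' @param states Optional `state_table`; if supplied, every state token is
#'   resolved against it (plus the `ANY` and `DEATH` tokens).
#' @return A `data.frame` of class `transition_table`.
#' @details Validation enforces: no duplicate `(from_state, to_state)`
#'   pair; `annual_prob` in \[0, 1) for all non-death rows; exactly one
#'   `to_state = DEATH` row, flagged `age_specific`, with no fixed
#'   probability (it is resolved from the life table at run time).
#' @export
read_transition_table <- function(path, states = NULL) {
  df <- read_checked_csv(path, TRANS_CSV_COLS)
  df$from_state <- as.character(df$from_state)
  df$to_state <- as.character(df$to_state)
  df$dist_family <- as.character(df$dist_family)
  df$derivation_flag <- as.character(df$derivation_flag)
  validate_transition_table(df, states = states)
}

#' Validate a transition table
#'
#' @inheritParams read_transition_table
#' @param df A data.frame with transition-table columns.
#' @return `df`, classed as `transition_table`.
#' @export
validate_transition_table <- function(df, states = NULL) {
  key <- paste(df$from_state, df$to_state, sep = "->")
  if (anyDuplicated(key))
    stop("transition table: duplicate (from_state, to_state) pair: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  bad_flag <- !df$derivation_flag %in% DERIVATION_FLAGS
  if (any(bad_flag))
    stop("transition table: unknown derivation_flag: ",
         paste(unique(df$derivation_flag[bad_flag]), collapse = ", "),
         call. = FALSE)
  death <- df$to_state == DEATH_TOKEN
  if (sum(death) != 1L)
    stop("transition table: exactly one 'to_state = DEATH' row is required; ",
         "found ", sum(death), call. = FALSE)
  if (df$derivation_flag[death] != "age_specific" || !is.na(df$annual_prob[death]))
    stop("transition table: the DEATH row must be flagged age_specific ",
         "with no fixed annual_prob (it is resolved from the life table)",
         call. = FALSE)
  for (i in which(!death)) {
    p <- df$annual_prob[i]
    if (!is.finite(p) || p < 0 || p >= 1)
      stop(sprintf("transition table row %d (%s -> %s): annual_prob must lie in [0, 1), got %s",
                   i, df$from_state[i], df$to_state[i], p), call. = FALSE)
    validate_dist_params(match.arg(df$dist_family[i],
                                   c("beta", "gamma", "lognormal", "fixed")),
                         df$dist_a[i], df$dist_b[i],
                         where = sprintf("transition %s -> %s dist",
                                         df$from_state[i], df$to_state[i]))
  }
  if (!is.null(states)) {
    known <- c(states$state_id, ANY_TOKEN)
    bad_from <- setdiff(df$from_state, known)
    bad_to <- setdiff(df$to_state, c(states$state_id, DEATH_TOKEN))
    if (length(bad_from) || length(bad_to))
      stop("transition table: unknown state token(s): ",
           paste(unique(c(bad_from, bad_to)), collapse = ", "), call. = FALSE)
    # each concrete from-state must leave a nonnegative stay probability
    # before mortality; the age-dependent check happens in build_matrix()
    edges <- expand_edges(states, df)
    exits <- tapply(edges$annual_prob, edges$from_state, sum)
    if (any(exits >= 1))
      stop("transition table: exit probabilities sum to >= 1 for state(s): ",
           paste(names(exits)[exits >= 1], collapse = ", "), call. = FALSE)
  }
  structure(df, class = c("transition_table", "data.frame"))
}

#' Expand wildcard rows into concrete directed edges
#'
#' `ANY -> to` rows apply from every alive state (including the healthy
#' reference state), except the target state itself and any from-state with
#' a specific `(from, to)` row, which overrides the wildcard.
#'
#' @param states A `state_table`.
#' @param transitions A `transition_table`.
#' @return A data.frame of concrete edges with columns `from_state`,
#'   `to_state`, `annual_prob`, `source_row` (row index in `transitions`)
#'   and `wildcard` (logical).
#' @export
expand_edges <- function(states, transitions) {
  tt <- transitions[transitions$to_state != DEATH_TOKEN, , drop = FALSE]
  idx <- seq_len(nrow(transitions))[transitions$to_state != DEATH_TOKEN]
  concrete <- tt$from_state != ANY_TOKEN
  out <- data.frame(from_state = tt$from_state[concrete],
                    to_state = tt$to_state[concrete],
                    annual_prob = tt$annual_prob[concrete],
                    source_row = idx[concrete],
                    wildcard = rep(FALSE, sum(concrete)),
                    stringsAsFactors = FALSE)
  have <- paste(out$from_state, out$to_state, sep = "->")
  expanded <- lapply(which(!concrete), function(j) {
    to <- tt$to_state[j]
    froms <- setdiff(states$state_id, to)
    froms <- froms[!paste(froms, to, sep = "->") %in% have]
    if (!length(froms)) return(NULL)
    data.frame(from_state = froms, to_state = to,
               annual_prob = tt$annual_prob[j], source_row = idx[j],
               wildcard = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(out), expanded))
  rownames(out) <- NULL
  out
}

#' Read and validate a life table
#'
#' @param path Path to a CSV with columns `age,qx`.
#' @return A `data.frame` of class `life_table` with integer `age` and
#'   `qx`, the annual probability of death at that age.
#' @details Ages must be contiguous integers and `qx` must lie in
#'   \[0, 1\]; monotonicity is not required (real tables wobble).
#' @export
read_life_table <- function(path) {
  df <- read_checked_csv(path, c("age", "qx"))
  validate_life_table(df)
}

#' Validate a life table
#' @param df A data.frame with columns `age` and `qx`.
#' @return `df`, ordered by age and classed as `life_table`.
#' @export
validate_life_table <- function(df) {
  df <- df[order(df$age), , drop = FALSE]
  if (any(df$age != round(df$age)))
    stop("life table: ages must be integers", call. = FALSE)
  if (nrow(df) > 1 && any(diff(df$age) != 1))
    stop("life table: ages must be contiguous", call. = FALSE)
  bad <- !is.finite(df$qx) | df$qx < 0 | df$qx > 1
  if (any(bad))
    stop("life table: qx must lie in [0, 1]; offending age(s): ",
         paste(df$age[bad], collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("life_table", "data.frame"))
}

#' Annual probability of death at a given age
#'
#' @param life_table A `life_table`.
#' @param age Age in whole years.
#' @return The annual death probability `qx` at `age`.
#' @export
mortality_at <- function(life_table, age) {
  i <- match(age, life_table$age)
  if (is.na(i))
    stop(sprintf(paste0("age %s is outside the life table range [%d, %d]; ",
                        "extend the life table to cover it"),
                 age, min(life_table$age), max(life_table$age)),
         call. = FALSE)
  life_table$qx[i]
}

# CSV reader with a header check shared by all three tables.
read_checked_csv <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(basename(path), ": missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df[, cols, drop = FALSE]
}
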