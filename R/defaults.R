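#' Packaged default model inputs
#'
#' The package ships a complete default parameterization of the
#' cardiometabolic model: 16 alive health states (healthy, obesity,
#' pre-diabetes, pre-hypertension, hypertension and stage-2 hypertension,
#' diabetes, ischemic heart disease, myocardial infarction, congestive
#' heart failure, stroke, the composite states, and high-risk diabetes)
#' with annual costs in 2023 USD and utility weights, the directed annual
#' transition probabilities among them (including `ANY ->` acute-event
#' rows and age-specific death), and a life table.
#'
#' The life table is a synthetic stand-in: a smooth Gompertz-type curve
#' `qx = 0.0004 + 6.67e-5 * exp(0.085 * age)` over ages 0–100, anchored
#' near published adult-US mortality magnitudes.  Substitute a real
#' national life table for production analyses via the scenario config.
#'
#' @return `lbc_default_states()`, `lbc_default_transitions()` and
#'   `lbc_default_life_table()` return the validated packaged tables;
#'   `lbc_default_scenario()` returns the packaged scenario config (whose
#'   baseline distribution and intervention effect sizes are illustrative
#'   defaults, flagged as such in the file).
#' @seealso [read_state_table()], [read_scenario()]
#' @export
lbc_default_states <- function() {
  read_state_table(lbc_extdata("states.csv"))
}

#' @rdname lbc_default_states
#' @export
lbc_default_transitions <- function() {
  read_transition_table(lbc_extdata("transitions.csv"), lbc_default_states())
}

#' @rdname lbc_default_states
#' @export
lbc_default_life_table <- function() {
  read_life_table(lbc_extdata("lifetable_synthetic.csv"))
}

#' @rdname lbc_default_states
#' @export
lbc_default_scenario <- function() {
  read_scenario(lbc_extdata("scenario.yaml"))
}

lbc_extdata <- function(file) {
  path <- system.file("extdata", file, package = "lbcroi")
  if (path == "") stop("packaged file not found: ", file, call. = FALSE)
  path
}

#' Load the model inputs named by a scenario config
#'
#' Resolves the optional `states_file`, `transitions_file` and
#' `lifetable_file` keys of a scenario (relative paths are interpreted
#' against the config's own directory), falling back to the packaged
#' defaults for any key that is absent.
#'
#' @param config A `scenario_config`.
#' @return A list with elements `states`, `transitions`, `life_table`.
#' @export
load_model_inputs <- function(config) {
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p) && !is.null(config$config_dir))
      p <- file.path(config$config_dir, p)
    p
  }
  sp <- resolve(config$states_file)
  states <- if (is.null(sp)) lbc_default_states() else read_state_table(sp)
  tp <- resolve(config$transitions_file)
  transitions <- if (is.null(tp)) {
    if (is.null(sp)) lbc_default_transitions()
    else read_transition_table(lbc_extdata("transitions.csv"), states)
  } else read_transition_table(tp, states)
  lp <- resolve(config$lifetable_file)
  life_table <- if (is.null(lp)) lbc_default_life_table() else read_life_table(lp)
  list(states = states, transitions = transitions, life_table = life_table)
}
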