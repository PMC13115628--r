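#' Total net savings
#'
#' `medication_savings + services_savings - program_costs`.  A negative
#' result is allowed and signals a net loss.
#'
#' @param medication_savings,services_savings Gross savings components, USD.
#' @param program_costs Program costs, USD (>= 0).
#' @return Net savings, USD.
#' @examples
#' compute_total_savings(9880784, 23055163, 4371780)  # 28564167
#' @export
compute_total_savings <- function(medication_savings, services_savings,
                                  program_costs) {
  if (program_costs < 0) stop("program_costs must be >= 0", call. = FALSE)
  medication_savings + services_savings - program_costs
}

#' Return on investment
#'
#' Net cost savings divided by program costs: the dollars returned per
#' dollar invested.
#'
#' @param net_savings Net savings, USD (may be negative).
#' @param program_costs Program costs, USD (> 0).
#' @return Dimensionless ratio.
#' @examples
#' round(compute_roi(28564167, 4371780), 2)  # 6.53
#' @export
compute_roi <- function(net_savings, program_costs) {
  if (!is.numeric(program_costs) || program_costs <= 0)
    stop("program_costs must be > 0: ROI is undefined otherwise",
         call. = FALSE)
  net_savings / program_costs
}

#' Convert a QALY gain to equivalent days of full health
#'
#' @param qaly_gain Incremental QALYs.
#' @return `qaly_gain * 365` days.
#' @examples
#' qaly_gain_to_days(0.1)  # 36.5
#' @export
qaly_gain_to_days <- function(qaly_gain) qaly_gain * 365

#' Economic summary of a treated-versus-control comparison
#'
#' Turns two cohort traces into the reporting surface of the analysis:
#' per-member, annual, monthly and population-level cost views for both
#' arms, the savings decomposition (medication vs healthcare services vs
#' program costs), the QALY gain and its days-of-full-health equivalent,
#' and the return on investment.
#'
#' Treated per-member cost includes the discounted program cost, so the
#' per-member saving is net of the program; consistently, the population
#' net savings equal gross medical savings minus program costs and the
#' ROI divides that net figure by program costs.  The medication /
#' services decomposition is presentational: a single configured fraction
#' allocates gross medical savings between the two lines (the ROI depends
#' only on their total), and services savings are computed as the exact
#' complement so the decomposition always closes.
#'
#' @param treated,control `cohort_trace` objects sharing the same horizon.
#' @param config A `scenario_config` (supplies population, the program
#'   cost override if any, and the default savings split).
#' @param savings_split Optional list with `medication_fraction`,
#'   overriding `config$savings_split`.
#' @return A list of class `econ_summary`; all USD fields at full
#'   precision (rounding happens in [econ_table()] / printing).
#' @export
econ_summary <- function(treated, control, config, savings_split = NULL) {
  if (treated$horizon != control$horizon)
    stop(sprintf("horizon mismatch: treated %d vs control %d",
                 treated$horizon, control$horizon), call. = FALSE)
  split <- if (is.null(savings_split)) config$savings_split else savings_split
  mf <- split$medication_fraction
  if (!is.numeric(mf) || mf < 0 || mf > 1)
    stop("savings_split$medication_fraction must lie in [0, 1]", call. = FALSE)
  N <- config$population
  h <- treated$horizon
  override <- config$program_cost_total_override

  program_pop <- if (!is.null(override)) override
                 else treated$total_program_disc * N
  pm_treated <- treated$total_medical_disc + program_pop / N
  pm_control <- control$total_medical_disc + control$total_program_disc
  pm_saving <- pm_control - pm_treated

  # gross medical savings are defined so that net savings == per-member
  # saving x population holds exactly even when the control trace itself
  # carries program costs (e.g. identical-trace null comparisons)
  gross_pop <- pm_saving * N + program_pop
  medication <- gross_pop * mf
  services <- gross_pop - medication      # exact complement: closure
  net <- compute_total_savings(medication, services, program_pop)
  roi <- if (program_pop > 0) compute_roi(net, program_pop) else
    if (net == 0) 0 else sign(net) * Inf

  qg <- treated$total_qaly_disc - control$total_qaly_disc
  structure(list(
    horizon = h, population = N,
    per_member_cost_treated = pm_treated,
    per_member_cost_control = pm_control,
    per_member_saving = pm_saving,
    annual_per_member_treated = pm_treated / h,
    annual_per_member_control = pm_control / h,
    monthly_per_member_treated = pm_treated / (12 * h),
    monthly_per_member_control = pm_control / (12 * h),
    population_cost_treated = pm_treated * N,
    population_cost_control = pm_control * N,
    gross_medical_savings = gross_pop,
    medication_savings = medication,
    services_savings = services,
    program_costs = program_pop,
    total_net_savings = net,
    qaly_treated = treated$total_qaly_disc,
    qaly_control = control$total_qaly_disc,
    qaly_gain = qg,
    qaly_gain_days = qaly_gain_to_days(qg),
    roi = roi), class = "econ_summary")
}

#' Tabular cost-comparison report
#'
#' Presentation table with one row per cost view (total, annual, monthly
#' per member; population total) and columns treated / control /
#' difference.  USD amounts are rounded to whole dollars and, matching
#' common reporting practice, the difference column is the difference of
#' the rounded per-arm figures.
#'
#' @param x An `econ_summary`.
#' @return A data.frame with columns `metric`, `treated`, `control`,
#'   `difference`.
#' @export
econ_table <- function(x) {
  r <- function(v) round(v)
  rows <- rbind(
    c(r(x$per_member_cost_treated), r(x$per_member_cost_control)),
    c(r(x$annual_per_member_treated), r(x$annual_per_member_control)),
    c(r(x$monthly_per_member_treated), r(x$monthly_per_member_control)),
    c(r(x$population_cost_treated), r(x$population_cost_control)))
  data.frame(
    metric = c(sprintf("Total cost per member (%d years)", x$horizon),
               "Annual cost per member", "Monthly cost per member",
               "Population total cost"),
    treated = rows[, 1], control = rows[, 2],
    difference = rows[, 2] - rows[, 1])
}

#' @export
print.econ_summary <- function(x, ...) {
  cat(sprintf("Economic summary over %d years, population %s\n",
              x$horizon, format(x$population, big.mark = ",")))
  tab <- econ_table(x)
  tab[, 2:4] <- lapply(tab[, 2:4], function(v)
    paste0("$", format(v, big.mark = ",", scientific = FALSE)))
  print(tab, row.names = FALSE, right = FALSE)
  usd <- function(v) paste0("$", format(round(v), big.mark = ",",
                                        scientific = FALSE))
  cat("Savings decomposition: medication", usd(x$medication_savings),
      "+ services", usd(x$services_savings),
      "- program", usd(x$program_costs),
      "=", usd(x$total_net_savings), "\n")
  cat(sprintf("QALYs: %.4f treated vs %.4f control (gain %.4f = %.1f days)\n",
              x$qaly_treated, x$qaly_control, x$qaly_gain, x$qaly_gain_days))
  cat(sprintf("ROI: %.2f\n", x$roi))
  invisible(x)
}

#' Write an economic summary to JSON and/or CSV
#'
#' @param x An `econ_summary`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_econ_summary <- function(x, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(x), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(csv_path)) {
    flat <- unclass(x)
    utils::write.csv(data.frame(field = names(flat),
                                value = unlist(flat, use.names = FALSE)),
                     csv_path, row.names = FALSE)
  }
  invisible(c(json_path, csv_path))
}
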