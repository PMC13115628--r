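#' @title Sensitivity analysis
#' @name sensitivity
#' @description Probabilistic sensitivity analysis (Monte Carlo over the
#'   parameter distributions) and deterministic one-way (tornado)
#'   sensitivity over user-named parameters.
NULL

# Named substreams derived from one top-level seed, so adding a new
# consumer of randomness never perturbs existing streams.  Knuth-style
# multiplicative mixing, kept below 2^31 for R's integer seeds.
substream_seed <- function(seed, stream = c("psa", "synthetic"), index = 0L) {
  stream <- match.arg(stream)
  tag <- sum(utf8ToInt(stream))
  ((as.double(seed) %% 2^31) * 69069 + tag * 2654435761 + index * 40503) %% 2^31
}

#' Draw one joint parameter set
#'
#' One probabilistic-sensitivity draw: state annual costs are sampled from
#' their gamma specs, utilities and transition probabilities from beta
#' distributions re-anchored so their mean equals the deterministic point
#' estimate while keeping the published effective sample size (alpha +
#' beta; see [rescale_beta_to_mean()]), and relative-risk multipliers from
#' a lognormal whose median is the base multiplier.  The healthy reference
#' state (cost 0, utility 1) anchors the QALY scale and is never sampled,
#' nor are degenerate specs (`fixed`, gamma scale 0).  Draws are
#' independent across parameters and use the current RNG state: seed
#' before calling for reproducibility.
#'
#' @param states A `state_table`.
#' @param transitions A `transition_table`.
#' @param rrr_base Optional named list of base relative-risk multipliers.
#' @param rrr_sigma Lognormal sdlog for the multipliers (default 0.1).
#' @return A list with sampled `states`, `transitions` and `rrr`.
#' @export
sample_parameters <- function(states, transitions, rrr_base = NULL,
                              rrr_sigma = 0.1) {
  st <- states
  ref <- attr(states, "reference_state")
  for (i in seq_len(nrow(st))) {
    if (st$state_id[i] == ref) next
    fam <- st$cost_dist_family[i]
    if (!(fam == "fixed" || (fam == "gamma" && st$cost_b[i] == 0)))
      st$annual_cost[i] <- draw_dist(fam, st$cost_a[i], st$cost_b[i])
    ufam <- st$utility_dist_family[i]
    if (ufam == "beta" && st$utility[i] > 0 && st$utility[i] < 1) {
      spec <- rescale_beta_to_mean(st$utility[i],
                                   st$utility_a[i] + st$utility_b[i])
      st$utility[i] <- draw_dist("beta", spec$a, spec$b)
    } else if (ufam != "fixed" && ufam != "beta") {
      st$utility[i] <- min(1, max(0, draw_dist(ufam, st$utility_a[i],
                                               st$utility_b[i])))
    }
  }
  tt <- transitions
  for (i in seq_len(nrow(tt))) {
    if (tt$to_state[i] == DEATH_TOKEN) next
    fam <- tt$dist_family[i]
    p <- tt$annual_prob[i]
    if (fam == "beta" && p > 0 && p < 1) {
      spec <- rescale_beta_to_mean(p, tt$dist_a[i] + tt$dist_b[i])
      tt$annual_prob[i] <- draw_dist("beta", spec$a, spec$b)
    } else if (!fam %in% c("fixed", "beta")) {
      tt$annual_prob[i] <- min(1 - 1e-12,
                               max(0, draw_dist(fam, tt$dist_a[i], tt$dist_b[i])))
    }
  }
  rrr <- rrr_base
  if (length(rrr) && rrr_sigma > 0) {
    for (k in names(rrr))
      rrr[[k]] <- min(1, draw_dist("lognormal", log(rrr_base[[k]]), rrr_sigma))
  }
  list(states = st, transitions = tt, rrr = rrr)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over the parameter distributions: each iteration draws one
#' joint parameter set with [sample_parameters()], runs both arms, and
#' records the ROI and incremental QALY gain.  Any sampled row whose exit
#' probabilities would exceed 1 is proportionally rescaled to 0.999 total
#' exits; the number of such events is counted and reported, keeping the
#' iteration count fixed.
#'
#' Each iteration is seeded from the PSA substream of `config$psa$seed`,
#' so re-running with the same seed reproduces every array bit-identically
#' and extending `n_iter` leaves earlier iterations unchanged.
#'
#' @param config A `scenario_config` (uses `psa$n_iter`, `psa$seed`,
#'   `psa$percentiles`, `psa$rrr_sigma`).
#' @param states,transitions,life_table Model inputs.
#' @return A list of class `psa_result`: `n_iter`, `seed`, per-iteration
#'   `roi` and `qaly_gain` vectors, `roi_mean`, `roi_ci` (empirical
#'   percentiles), `qaly_gain_mean`, and `overflow_events`.
#' @export
run_psa <- function(config, states, transitions, life_table) {
  n <- as.integer(config$psa$n_iter)
  if (n < 1) stop("psa$n_iter must be >= 1", call. = FALSE)
  validate_scenario(config, states = states, transitions = transitions)
  seed <- config$psa$seed
  roi <- qaly_gain <- numeric(n)
  overflow <- 0L
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, "psa", index = i))
    draw <- tryCatch(
      sample_parameters(states, transitions,
                        rrr_base = config$intervention_rrr,
                        rrr_sigma = config$psa$rrr_sigma),
      error = function(e)
        stop(sprintf("PSA iteration %d: %s", i, conditionMessage(e)),
             call. = FALSE))
    cfg_i <- config
    cfg_i$intervention_rrr <- draw$rrr
    res <- tryCatch({
      ctrl <- run_cohort(cfg_i, draw$states, draw$transitions, life_table,
                         arm = "control", overflow = "rescale",
                         validate = FALSE)
      trt <- run_cohort(cfg_i, draw$states, draw$transitions, life_table,
                        arm = "intervention", overflow = "rescale",
                        validate = FALSE)
      list(ctrl = ctrl, trt = trt)
    }, error = function(e)
      stop(sprintf("PSA iteration %d: %s", i, conditionMessage(e)),
           call. = FALSE))
    overflow <- overflow + res$ctrl$overflow_events + res$trt$overflow_events
    s <- econ_summary(res$trt, res$ctrl, cfg_i)
    roi[i] <- s$roi
    qaly_gain[i] <- s$qaly_gain
  }
  if (overflow > 0)
    message(sprintf(
      "PSA: %d sampled row(s) had exits > 1 and were rescaled to 0.999",
      overflow))
  ci <- stats::quantile(roi, probs = config$psa$percentiles, names = FALSE,
                        type = 7)
  structure(list(n_iter = n, seed = seed, roi = roi, qaly_gain = qaly_gain,
                 roi_mean = mean(roi), roi_ci = ci,
                 qaly_gain_mean = mean(qaly_gain),
                 percentiles = config$psa$percentiles,
                 overflow_events = overflow),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %s)\n", x$n_iter,
              format(x$seed, scientific = FALSE)))
  cat(sprintf("  ROI mean %.3f (%.1f%%-%.1f%% CI: %.3f to %.3f)\n",
              x$roi_mean, 100 * x$percentiles[1], 100 * x$percentiles[2],
              x$roi_ci[1], x$roi_ci[2]))
  cat(sprintf("  QALY gain mean %.5f\n", x$qaly_gain_mean))
  if (x$overflow_events > 0)
    cat(sprintf("  %d sampled row(s) rescaled for exit overflow\n",
                x$overflow_events))
  invisible(x)
}

# Resolve a tornado parameter name to a setter returning modified inputs.
tornado_setters <- function(config, states, transitions) {
  edge_keys <- paste(transitions$from_state, transitions$to_state, sep = "->")
  edge_keys <- edge_keys[transitions$to_state != DEATH_TOKEN]
  valid <- c("program_cost_per_member_year", "discount_rate",
             paste0("cost:", states$state_id),
             paste0("utility:", states$state_id),
             paste0("prob:", edge_keys),
             paste0("rrr:", names(config$intervention_rrr)))
  set <- function(name, value) {
    cfg <- config; st <- states; tt <- transitions
    if (name %in% c("program_cost_per_member_year", "discount_rate")) {
      cfg[[name]] <- value
    } else if (startsWith(name, "cost:")) {
      st$annual_cost[st$state_id == sub("^cost:", "", name)] <- value
    } else if (startsWith(name, "utility:")) {
      st$utility[st$state_id == sub("^utility:", "", name)] <- value
    } else if (startsWith(name, "prob:")) {
      key <- sub("^prob:", "", name)
      ft <- parse_edge_key(key)
      hit <- tt$from_state == ft[1] & tt$to_state == ft[2]
      tt$annual_prob[hit] <- value
    } else if (startsWith(name, "rrr:")) {
      cfg$intervention_rrr[[sub("^rrr:", "", name)]] <- value
    }
    list(config = cfg, states = st, transitions = tt)
  }
  list(valid = valid, set = set)
}

#' One-way deterministic (tornado) sensitivity analysis
#'
#' Each named parameter is set in turn to its low and high bound with all
#' other parameters at base case, the deterministic model is re-run, and
#' the resulting ROIs are reported, sorted by swing (|roi_at_high -
#' roi_at_low|) descending.
#'
#' @param config A `scenario_config`.
#' @param parameter_ranges Named list mapping a parameter name to
#'   `c(low, high)`.  Valid names: `program_cost_per_member_year`,
#'   `discount_rate`, `cost:<state_id>`, `utility:<state_id>`,
#'   `prob:<From->To>`, `rrr:<edge>`.
#' @param states,transitions,life_table Model inputs.
#' @return A data.frame of class `tornado_result` with columns `name`,
#'   `low_value`, `high_value`, `roi_at_low`, `roi_at_high`, `swing`, plus
#'   attribute `base_roi`.
#' @export
run_tornado <- function(config, parameter_ranges, states, transitions,
                        life_table) {
  ts <- tornado_setters(config, states, transitions)
  bad <- setdiff(names(parameter_ranges), ts$valid)
  if (length(bad))
    stop("unresolvable parameter name(s): ", paste(bad, collapse = ", "),
         "\nvalid names: ", paste(ts$valid, collapse = ", "), call. = FALSE)
  roi_of <- function(cfg, st, tt) {
    ctrl <- run_cohort(cfg, st, tt, life_table, arm = "control")
    trt <- run_cohort(cfg, st, tt, life_table, arm = "intervention")
    econ_summary(trt, ctrl, cfg)$roi
  }
  base_roi <- roi_of(config, states, transitions)
  rows <- lapply(names(parameter_ranges), function(nm) {
    rng <- parameter_ranges[[nm]]
    lo <- ts$set(nm, rng[1]); hi <- ts$set(nm, rng[2])
    data.frame(name = nm, low_value = rng[1], high_value = rng[2],
               roi_at_low = roi_of(lo$config, lo$states, lo$transitions),
               roi_at_high = roi_of(hi$config, hi$states, hi$transitions))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), low_value = numeric(),
               high_value = numeric(), roi_at_low = numeric(),
               roi_at_high = numeric())
  out$swing <- abs(out$roi_at_high - out$roi_at_low)
  out <- out[order(-out$swing), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, base_roi = base_roi,
            class = c("tornado_result", "data.frame"))
}
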