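#' Uncertainty distribution specifications
#'
#' Parameter uncertainty is described by a small family of distributions,
#' following standard health-economic practice: beta for probabilities and
#' utilities, gamma for costs, lognormal for relative-risk multipliers, and
#' `fixed` for parameters that are not sampled.  A spec is a triple
#' `(family, a, b)` whose meaning depends on the family:
#'
#' * `beta`: shape parameters `a` (alpha) and `b` (beta), both > 0;
#' * `gamma`: shape `a` > 0 and scale `b` >= 0 (mean = `a * b`; scale 0 is
#'   treated as degenerate at 0, used for the zero-cost reference state);
#' * `lognormal`: `a` = meanlog, `b` = sdlog > 0;
#' * `fixed`: the value `a`; `b` is ignored.
#'
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`.
#' @param a,b Numeric parameters, interpreted per family as above.
#' @return A list of class `dist_spec` with elements `family`, `a`, `b`.
#' @examples
#' dist_spec("gamma", 100, 95)   # mean 9500, the diabetes annual cost
#' dist_spec("beta", 70, 30)     # mean 0.7, the diabetes utility
#' @export
dist_spec <- function(family, a = NA_real_, b = NA_real_) {
  family <- match.arg(family, c("beta", "gamma", "lognormal", "fixed"))
  validate_dist_params(family, a, b, where = "dist_spec")
  structure(list(family = family, a = as.numeric(a), b = as.numeric(b)),
            class = "dist_spec")
}

# Shared parameter checks; `where` names the offending row/field in errors.
validate_dist_params <- function(family, a, b, where = "distribution") {
  chk <- function(ok, msg) {
    if (!isTRUE(ok)) stop(sprintf("%s: %s", where, msg), call. = FALSE)
  }
  switch(family,
    beta = {
      chk(is.finite(a) && a > 0, sprintf("beta alpha must be > 0 (got %s)", a))
      chk(is.finite(b) && b > 0, sprintf("beta beta must be > 0 (got %s)", b))
    },
    gamma = {
      chk(is.finite(a) && a > 0, sprintf("gamma shape must be > 0 (got %s)", a))
      chk(is.finite(b) && b >= 0, sprintf("gamma scale must be >= 0 (got %s)", b))
    },
    lognormal = {
      chk(is.finite(a), sprintf("lognormal meanlog must be finite (got %s)", a))
      chk(is.finite(b) && b > 0, sprintf("lognormal sdlog must be > 0 (got %s)", b))
    },
    fixed = {
      chk(is.finite(a), sprintf("fixed value must be finite (got %s)", a))
    }
  )
  invisible(TRUE)
}

#' Re-anchor a beta distribution to a point estimate
#'
#' Returns a beta spec whose mean equals `point_estimate` exactly while the
#' effective sample size (alpha + beta) equals `effective_n`.  Published
#' beta parameters for transition probabilities are often inconsistent with
#' the published point estimates; deterministic runs use the point estimate,
#' and probabilistic runs use the rescaled spec produced here, which keeps
#' the published spread (via alpha + beta) but forces the mean back onto the
#' point estimate.
#'
#' @param point_estimate Probability in (0, 1); the target mean.
#' @param effective_n Positive real; alpha + beta of the returned spec.
#' @return A `dist_spec` with `family = "beta"`,
#'   `a = point_estimate * effective_n`, `b = (1 - point_estimate) * effective_n`.
#' @examples
#' rescale_beta_to_mean(0.0246, 1000)  # Beta(24.6, 975.4), mean 0.0246
#' rescale_beta_to_mean(0.88, 1000)    # Beta(880, 120)
#' @export
rescale_beta_to_mean <- function(point_estimate, effective_n) {
  if (!is.finite(point_estimate) || point_estimate <= 0 || point_estimate >= 1)
    stop("point_estimate must lie strictly in (0, 1); ",
         "use a 'fixed' spec for degenerate probabilities", call. = FALSE)
  if (!is.finite(effective_n) || effective_n <= 0)
    stop("effective_n must be > 0", call. = FALSE)
  dist_spec("beta",
            a = point_estimate * effective_n,
            b = (1 - point_estimate) * effective_n)
}

#' Draw from a distribution specification
#'
#' @param family,a,b A distribution spec, unpacked (see [dist_spec()]).
#' @param n Number of draws.
#' @return Numeric vector of length `n`.  Degenerate specs (`fixed`, or
#'   gamma with scale 0) return their point value without consuming random
#'   numbers, so adding non-sampled parameters never perturbs the stream.
#' @export
draw_dist <- function(family, a, b, n = 1) {
  switch(family,
    beta      = stats::rbeta(n, shape1 = a, shape2 = b),
    gamma     = if (b == 0) rep(0, n) else stats::rgamma(n, shape = a, scale = b),
    lognormal = stats::rlnorm(n, meanlog = a, sdlog = b),
    fixed     = rep(a, n),
    stop("unknown distribution family: ", family, call. = FALSE)
  )
}
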