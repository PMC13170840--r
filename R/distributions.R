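#' Probabilistic sensitivity analysis distribution specification
#'
#' Describes how an uncertain parameter is sampled in the probabilistic
#' sensitivity analysis.  Following the usual good-practice assignment,
#' probabilities, proportions and utilities take beta distributions, costs
#' and disutility magnitudes take gamma, and rate ratios take lognormal;
#' `normal` and degenerate `fixed` are also available and any parameter may
#' override its default family.
#'
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"normal"`,
#'   `"fixed"`.
#' @param params Named numeric parameters: `shape1`/`shape2` (beta),
#'   `shape`/`rate` (gamma), `meanlog`/`sdlog` (lognormal), `mean`/`sd`
#'   (normal), `value` (fixed).
#' @return A list of class `dist_spec`.
#' @export
dist_spec <- function(family, params) {
  s <- list(family = family, params = params)
  class(s) <- "dist_spec"
  validate_dist_spec(s, "dist_spec")
  s
}

validate_dist_spec <- function(spec, path) {
  fam <- spec$family
  p <- spec$params
  ok <- switch(fam,
    beta = all(c("shape1", "shape2") %in% names(p)) &&
      p[["shape1"]] > 0 && p[["shape2"]] > 0,
    gamma = all(c("shape", "rate") %in% names(p)) &&
      p[["shape"]] > 0 && p[["rate"]] > 0,
    lognormal = all(c("meanlog", "sdlog") %in% names(p)) && p[["sdlog"]] >= 0,
    normal = all(c("mean", "sd") %in% names(p)) && p[["sd"]] >= 0,
    fixed = "value" %in% names(p),
    stop(path, ": unknown distribution family '", fam, "'", call. = FALSE)
  )
  if (!isTRUE(ok)) {
    stop(path, ": invalid parameters for family '", fam, "'", call. = FALSE)
  }
  invisible(spec)
}

#' Mean of a distribution specification
#'
#' @param spec A [dist_spec()].
#' @return The analytic mean of the sampling distribution.
#' @export
dist_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
    beta = p[["shape1"]] / (p[["shape1"]] + p[["shape2"]]),
    gamma = p[["shape"]] / p[["rate"]],
    lognormal = exp(p[["meanlog"]] + p[["sdlog"]]^2 / 2),
    normal = p[["mean"]],
    fixed = p[["value"]]
  )
}

#' Sample from a distribution specification
#'
#' Uses the current RNG state; callers that need per-parameter streams seed
#' before each call.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
    beta = stats::rbeta(n, p[["shape1"]], p[["shape2"]]),
    gamma = stats::rgamma(n, shape = p[["shape"]], rate = p[["rate"]]),
    lognormal = stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]]),
    normal = stats::rnorm(n, p[["mean"]], p[["sd"]]),
    fixed = rep(p[["value"]], n)
  )
}

#' Build a default distribution spec for a point estimate
#'
#' Method-of-moments construction at a given coefficient of variation:
#' beta for quantities bounded in \[0, 1\], gamma for non-negative
#' magnitudes, lognormal for rate ratios (centred so the mean equals the
#' point estimate), normal as a symmetric fallback.  A zero point estimate
#' collapses to `fixed`.
#'
#' @param value Point estimate.
#' @param kind One of `"probability"`, `"cost"`, `"rr"`, `"symmetric"`.
#' @param cv Coefficient of variation of the sampling distribution.
#' @return A [dist_spec()].
#' @export
default_dist_spec <- function(value, kind = c("probability", "cost", "rr",
                                              "symmetric"), cv = 0.1) {
  kind <- match.arg(kind)
  if (value == 0) return(dist_spec("fixed", c(value = 0)))
  sd <- cv * abs(value)
  switch(kind,
    probability = {
      v <- sd^2
      # keep the variance feasible for a beta with this mean
      v <- min(v, 0.9 * value * (1 - value))
      nu <- value * (1 - value) / v - 1
      dist_spec("beta", c(shape1 = value * nu, shape2 = (1 - value) * nu))
    },
    cost = dist_spec("gamma", c(shape = 1 / cv^2, rate = 1 / (cv^2 * value))),
    rr = {
      sdlog <- sqrt(log(1 + cv^2))
      dist_spec("lognormal", c(meanlog = log(value) - sdlog^2 / 2,
                               sdlog = sdlog))
    },
    symmetric = dist_spec("normal", c(mean = value, sd = sd))
  )
}
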