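#' Standard deviation from a printed 95% interval
#'
#' Published decision-model parameter tables usually report a point estimate
#' with a low-high range rather than a standard deviation. When that range is
#' read as a 95% interval of an approximately normal sampling distribution,
#' the implied standard deviation is `(high - low) / 3.92`.
#'
#' @param low,high Interval endpoints; `high` must be at least `low`.
#' @return Nonnegative standard deviation; 0 for a degenerate range.
#' @examples
#' sd_from_range(0.65, 0.93)
#' @export
sd_from_range <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high))
  if (any(high < low)) {
    stop("sd_from_range(): 'high' must be >= 'low' (got ",
         low[which(high < low)[1]], " to ", high[which(high < low)[1]], ")")
  }
  (high - low) / 3.92
}

#' Method-of-moments beta distribution fit
#'
#' Solves for the shape parameters of a beta distribution with the given mean
#' and standard deviation. Used to turn a published probability estimate and
#' its uncertainty interval into a sampling distribution for probabilistic
#' sensitivity analysis.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#' @return Named list with `shape1` (alpha) and `shape2` (beta).
#' @examples
#' fit_beta(0.82, sd_from_range(0.65, 0.93))
#' @export
fit_beta <- function(mean, sd) {
  stopifnot(length(mean) == 1L, length(sd) == 1L)
  if (!(mean > 0 && mean < 1)) {
    stop("fit_beta(): mean must lie strictly in (0, 1), got ", mean)
  }
  if (sd <= 0) stop("fit_beta(): sd must be positive, got ", sd)
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("fit_beta(): infeasible moments, sd^2 = ", signif(v, 6),
         " >= mean*(1-mean) = ", signif(mean * (1 - mean), 6))
  }
  nu <- mean * (1 - mean) / v - 1
  list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Method-of-moments gamma distribution fit
#'
#' @param mean,sd Positive mean and standard deviation.
#' @return Named list with `shape` and `rate` such that `shape / rate == mean`
#'   and `shape / rate^2 == sd^2`.
#' @examples
#' fit_gamma(9.4, sd_from_range(8.1, 10.7))
#' @export
fit_gamma <- function(mean, sd) {
  stopifnot(length(mean) == 1L, length(sd) == 1L)
  if (mean <= 0 || sd <= 0) {
    stop("fit_gamma(): mean and sd must be positive, got mean = ", mean,
         ", sd = ", sd)
  }
  shape <- (mean / sd)^2
  list(shape = shape, rate = shape / mean)
}

# Resolve one uncertainty spec into a sampling function of n.
# Draw order inside each family is a documented part of PSA reproducibility:
# truncated normals resample rejected values until all n are in range.
.make_sampler <- function(spec, base) {
  family <- spec$family
  if (identical(family, "fixed")) {
    return(function(n) rep(base, n))
  }
  sd <- if (!is.null(spec$sd)) {
    spec$sd
  } else {
    sd_from_range(spec$low, spec$high)
  }
  if (sd <= 0) {
    return(function(n) rep(base, n))
  }
  switch(family,
    beta = {
      fit <- fit_beta(base, sd)
      function(n) stats::rbeta(n, fit$shape1, fit$shape2)
    },
    gamma = {
      fit <- fit_gamma(base, sd)
      function(n) stats::rgamma(n, shape = fit$shape, rate = fit$rate)
    },
    normal = {
      lo <- spec$low
      hi <- spec$high
      function(n) {
        x <- stats::rnorm(n, base, sd)
        bad <- which(x < lo | x > hi)
        while (length(bad) > 0L) {
          x[bad] <- stats::rnorm(length(bad), base, sd)
          bad <- bad[x[bad] < lo | x[bad] > hi]
        }
        x
      }
    },
    stop("unknown distribution family: ", family)
  )
}

# Analytic mean of the fitted sampling distribution (for diagnostics and
# convergence checks). For the truncated normal this is not the base value.
.sampler_mean <- function(spec, base) {
  family <- spec$family
  if (identical(family, "fixed")) return(base)
  sd <- if (!is.null(spec$sd)) spec$sd else sd_from_range(spec$low, spec$high)
  if (sd <= 0) return(base)
  if (identical(family, "normal")) {
    a <- (spec$low - base) / sd
    b <- (spec$high - base) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    return(base + sd * (stats::dnorm(a) - stats::dnorm(b)) / z)
  }
  base
}

# Analytic sd of the fitted sampling distribution.
.sampler_sd <- function(spec, base) {
  family <- spec$family
  if (identical(family, "fixed")) return(0)
  sd <- if (!is.null(spec$sd)) spec$sd else sd_from_range(spec$low, spec$high)
  if (sd <= 0) return(0)
  if (identical(family, "normal")) {
    a <- (spec$low - base) / sd
    b <- (spec$high - base) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    da <- stats::dnorm(a)
    db <- stats::dnorm(b)
    fa <- if (is.finite(a)) a * da else 0
    fb <- if (is.finite(b)) b * db else 0
    v <- 1 + (fa - fb) / z - ((da - db) / z)^2
    return(sd * sqrt(v))
  }
  sd
}
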