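# Inverse-gamma convention, fixed package-wide:
#   X ~ IG(shape, rate)  <=>  density f(x) proportional to x^(-shape-1) * exp(-rate/x)
# i.e. 1/X ~ Gamma(shape, rate). All Gibbs conditionals in the package are
# stated and sampled in this convention.

# smallest admissible IG rate; guards against zero-rate degeneracies
.IG_RATE_FLOOR <- 1e-300
# clamp for local variances: horseshoe tails overflow double precision
.LAMBDA2_MIN <- 1e-12
.LAMBDA2_MAX <- 1e12

#' Inverse-gamma random draws
#'
#' Draws from the inverse-gamma distribution parameterised by `shape` and
#' `rate`, with density proportional to `x^(-shape-1) * exp(-rate/x)`
#' (equivalently `1/X ~ Gamma(shape, rate)`). Rates are floored at a tiny
#' positive value so that degenerate zero-rate conditionals cannot produce
#' non-finite draws.
#'
#' @param n number of draws.
#' @param shape positive shape parameter (recycled).
#' @param rate positive rate parameter (recycled).
#' @return numeric vector of positive draws.
#' @export
rinvgamma <- function(n, shape, rate) {
  1 / rgamma(n, shape = shape, rate = pmax(rate, .IG_RATE_FLOOR))
}

#' Inverse-gamma density
#' @param x quantiles.
#' @inheritParams rinvgamma
#' @param log return log-density?
#' @return density (or log-density) values.
#' @export
dinvgamma <- function(x, shape, rate, log = FALSE) {
  n <- max(length(x), length(shape), length(rate))
  x <- rep_len(x, n); shape <- rep_len(shape, n); rate <- rep_len(rate, n)
  ld <- rep_len(-Inf, n)
  ok <- x > 0
  ld[ok] <- shape[ok] * base::log(rate[ok]) - lgamma(shape[ok]) -
    (shape[ok] + 1) * base::log(x[ok]) - rate[ok] / x[ok]
  if (log) ld else exp(ld)
}

#' Inverse-gamma distribution function
#' @param q quantiles.
#' @inheritParams rinvgamma
#' @return P(X <= q).
#' @export
pinvgamma <- function(q, shape, rate) {
  pgamma(1 / q, shape = shape, rate = rate, lower.tail = FALSE)
}

#' Inverse-gamma quantile function
#' @param p probabilities.
#' @inheritParams rinvgamma
#' @return quantiles.
#' @export
qinvgamma <- function(p, shape, rate) {
  1 / qgamma(1 - p, shape = shape, rate = rate)
}

#' Half-Cauchy draws and distribution function
#'
#' `rhalf_cauchy()` draws |C(0, scale)|; `phalf_cauchy()` is its CDF,
#' `2/pi * atan(q/scale)`. The half-Cauchy is the df = 1 member of the
#' half-t family and is the local/global scale prior of the Horseshoe and
#' Horseshoe+ hierarchies.
#'
#' @param n number of draws.
#' @param scale positive scale parameter.
#' @return draws, or CDF values.
#' @export
rhalf_cauchy <- function(n, scale = 1) {
  abs(rcauchy(n, location = 0, scale = scale))
}

#' @rdname rhalf_cauchy
#' @param q quantiles.
#' @export
phalf_cauchy <- function(q, scale = 1) {
  ifelse(q <= 0, 0, 2 / pi * atan(q / scale))
}

# clamp local variances into the representable band
clamp_lambda2 <- function(x) pmin(pmax(x, .LAMBDA2_MIN), .LAMBDA2_MAX)
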