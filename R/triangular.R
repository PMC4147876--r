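#' Triangular distribution
#'
#' All stochastic model inputs (annual failure probabilities, the repair-period
#' satisfaction adjustment, and optionally the treatment-complexity cost
#' factor) are described by triangular distributions, the usual choice when a
#' parameter is elicited as a most likely value plus a plausible range. A
#' degenerate triangle with `low == mode == high` is permitted and represents a
#' point mass, which is how fixed point estimates enter the same machinery.
#'
#' @param low Distribution minimum.
#' @param mode Most likely value; must satisfy `low <= mode <= high`.
#' @param high Distribution maximum.
#'
#' @return An object of class `"tri"`.
#' @examples
#' d <- tri(0.014, 0.018, 0.023)
#' tri_mean(d)
#' tri_quantile(d, c(0.025, 0.5, 0.975))
#' @export
tri <- function(low, mode, high) {
  stopifnot(is.numeric(low), is.numeric(mode), is.numeric(high),
            length(low) == 1L, length(mode) == 1L, length(high) == 1L)
  if (is.na(low) || is.na(mode) || is.na(high)) {
    rlang::abort("triangular parameters must not be NA", class = "odcea_invalid_tri")
  }
  if (!(low <= mode && mode <= high)) {
    rlang::abort(
      sprintf("invalid triangular distribution: need low <= mode <= high, got (%g, %g, %g)",
              low, mode, high),
      class = "odcea_invalid_tri"
    )
  }
  structure(list(low = low, mode = mode, high = high), class = "tri")
}

#' @export
print.tri <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.tri <- function(x, ...) {
  if (is_point_mass(x)) {
    sprintf("Triangular point mass at %g", x$mode)
  } else {
    sprintf("Triangular(min = %g, mode = %g, max = %g)", x$low, x$mode, x$high)
  }
}

#' Test for the `tri` class
#' @param x Object to test.
#' @return `TRUE` for objects created by [tri()].
#' @export
is_tri <- function(x) inherits(x, "tri")

is_point_mass <- function(d) d$low == d$high

#' Mean of a triangular distribution
#'
#' The closed-form first moment `(low + mode + high) / 3`, used for Monte Carlo
#' convergence checks.
#'
#' @param d A [tri()] distribution.
#' @return The mean as a scalar.
#' @export
tri_mean <- function(d) {
  stopifnot(is_tri(d))
  (d$low + d$mode + d$high) / 3
}

#' Triangular quantile function (inverse CDF)
#'
#' Maps uniform variates on `[0, 1]` to the triangular law, which is how every
#' probabilistic-sensitivity-analysis draw is generated: the sampler consumes
#' one uniform per parameter so that draws are reproducible and strictly
#' increasing in `p` whenever the distribution is non-degenerate.
#'
#' @param d A [tri()] distribution.
#' @param p Vector of probabilities in `[0, 1]`.
#' @return Quantiles, guaranteed to lie in `[low, high]`.
#' @export
tri_quantile <- function(d, p) {
  stopifnot(is_tri(d), is.numeric(p))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    rlang::abort("quantile probabilities must lie in [0, 1]",
                 class = "odcea_invalid_probability")
  }
  if (is_point_mass(d)) return(rep(d$mode, length(p)))
  width <- d$high - d$low
  f <- (d$mode - d$low) / width
  q <- ifelse(
    p < f,
    d$low + sqrt(p * width * (d$mode - d$low)),
    d$high - sqrt((1 - p) * width * (d$high - d$mode))
  )
  pmin(pmax(q, d$low), d$high)
}

#' Triangular cumulative distribution function
#'
#' @param d A [tri()] distribution.
#' @param q Vector of quantiles.
#' @return `P(X <= q)`.
#' @export
tri_cdf <- function(d, q) {
  stopifnot(is_tri(d), is.numeric(q))
  if (is_point_mass(d)) return(as.numeric(q >= d$mode))
  width <- d$high - d$low
  out <- numeric(length(q))
  below <- q <= d$low
  above <- q >= d$high
  left <- !below & !above & q <= d$mode
  right <- !below & !above & q > d$mode
  out[below] <- 0
  out[above] <- 1
  if (d$mode > d$low) {
    out[left] <- (q[left] - d$low)^2 / (width * (d$mode - d$low))
  } else {
    out[left] <- 0
  }
  if (d$high > d$mode) {
    out[right] <- 1 - (d$high - q[right])^2 / (width * (d$high - d$mode))
  } else {
    out[right] <- 1
  }
  out
}

#' Sample from a triangular distribution
#'
#' Inverse-CDF sampling driven by [stats::runif()]; seed the session RNG for
#' reproducibility.
#'
#' @param n Number of samples.
#' @param d A [tri()] distribution.
#' @return Numeric vector of length `n` within `[low, high]`.
#' @export
rtri <- function(n, d) {
  tri_quantile(d, stats::runif(n))
}
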