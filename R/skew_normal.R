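#' Skew-normal population specification
#'
#' Bundles the three parameters of the skew-normal family: location `xi`,
#' scale `omega` (> 0), and slant `alpha`. With `alpha = 0` the family
#' reduces to the normal distribution; `xi = 0, omega = 1, alpha = 0` is the
#' standard normal. The slant-derived quantity `gamma = alpha / sqrt(1 +
#' alpha^2)` enters every moment formula, so it is computed once and stored
#' on the object.
#'
#' @param xi Location parameter (real).
#' @param omega Scale parameter (real, strictly positive).
#' @param alpha Slant/shape parameter (real); positive values skew right.
#' @return An object of class `"sn_spec"`: a list with fields `xi`, `omega`,
#'   `alpha`, and the derived `gamma`.
#' @examples
#' sn_spec(0, 1, 0)   # standard normal
#' sn_spec(0, 1, 10)  # strongly right-skewed
#' @export
sn_spec <- function(xi, omega, alpha) {
  stopifnot(is.numeric(xi), length(xi) == 1L, is.finite(xi),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) ||
      omega <= 0) {
    stop("'omega' must be a single finite value > 0", call. = FALSE)
  }
  structure(
    list(xi = as.numeric(xi), omega = as.numeric(omega),
         alpha = as.numeric(alpha),
         gamma = alpha / sqrt(1 + alpha^2)),
    class = "sn_spec"
  )
}

#' @export
print.sn_spec <- function(x, ...) {
  m <- sn_moments(x)
  cat(sprintf("Skew-normal: xi = %.5g, omega = %.5g, alpha = %.5g\n",
              x$xi, x$omega, x$alpha))
  cat(sprintf("  implied mean = %.5g, sd = %.5g\n", m[["mean"]], m[["sd"]]))
  invisible(x)
}

#' Skew-normal density
#'
#' Density of the skew-normal distribution,
#' `f(y) = (2/omega) * phi(z) * Phi(alpha * z)` with `z = (y - xi)/omega`,
#' equivalently written with the error function as
#' `phi(z)/omega * (1 + erf(alpha * z / sqrt(2)))`.
#'
#' @param y Numeric vector of evaluation points.
#' @param spec An [sn_spec()] object.
#' @return Numeric vector of densities (nonnegative), same length as `y`.
#' @examples
#' sn_pdf(0, sn_spec(0, 1, 0))  # 1/sqrt(2*pi)
#' @export
sn_pdf <- function(y, spec) {
  stopifnot(inherits(spec, "sn_spec"))
  z <- (y - spec$xi) / spec$omega
  2 / spec$omega * stats::dnorm(z) * stats::pnorm(spec$alpha * z)
}

#' Mean and standard deviation of a skew-normal distribution
#'
#' With `gamma = alpha / sqrt(1 + alpha^2)`, the population mean is
#' `xi + omega * gamma * sqrt(2/pi)` and the variance is
#' `omega^2 * (1 - 2 * gamma^2 / pi)`.
#'
#' @param spec An [sn_spec()] object.
#' @return Named numeric vector `c(mean = , sd = )`.
#' @examples
#' sn_moments(sn_spec(0, 1, 10))
#' @export
sn_moments <- function(spec) {
  stopifnot(inherits(spec, "sn_spec"))
  g <- spec$gamma
  c(mean = spec$xi + spec$omega * g * sqrt(2 / pi),
    sd   = spec$omega * sqrt(1 - 2 * g^2 / pi))
}

#' Skew-normal parameters matching a target mean and SD
#'
#' Inverts the moment formulas: given a target population mean `mu`,
#' standard deviation `sigma`, and slant `alpha`, returns the `(xi, omega)`
#' pair whose skew-normal distribution has exactly those first two moments:
#' `omega = sigma / sqrt(1 - 2*gamma^2/pi)`, `xi = mu - omega * gamma *
#' sqrt(2/pi)`.
#'
#' @param mu Target population mean.
#' @param sigma Target population SD (> 0).
#' @param alpha Slant parameter.
#' @return An [sn_spec()] object whose moments reproduce `(mu, sigma)`.
#' @examples
#' spec <- sn_params_from_moments(2, 5, 10)
#' sn_moments(spec)  # c(2, 5) up to rounding
#' @export
sn_params_from_moments <- function(mu, sigma, alpha) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a single finite value > 0", call. = FALSE)
  }
  g <- alpha / sqrt(1 + alpha^2)
  omega <- sigma / sqrt(1 - 2 * g^2 / pi)
  xi <- mu - omega * g * sqrt(2 / pi)
  sn_spec(xi, omega, alpha)
}

#' Draw a skew-normal sample
#'
#' Samples via the exact stochastic representation: with `U`, `V`
#' independent standard normals and `gamma` the slant-derived quantity,
#' `Z = gamma * |U| + sqrt(1 - gamma^2) * V` is standard skew-normal with
#' shape `alpha`, and `Y = xi + omega * Z`. Rejection-free and O(n).
#'
#' @param n Number of draws (>= 1).
#' @param spec An [sn_spec()] object.
#' @param seed Optional integer; when supplied the RNG is seeded first so
#'   the draw is reproducible in isolation. When `NULL` the current RNG
#'   stream is used (the simulation engine manages seeds itself).
#' @return Numeric vector of length `n`.
#' @examples
#' y <- sn_sample(5, sn_spec(0, 1, 10), seed = 1)
#' @export
sn_sample <- function(n, spec, seed = NULL) {
  stopifnot(inherits(spec, "sn_spec"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- spec$gamma
  u <- abs(stats::rnorm(n))
  v <- stats::rnorm(n)
  spec$xi + spec$omega * (g * u + sqrt(1 - g^2) * v)
}
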