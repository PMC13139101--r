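#' Simulation condition
#'
#' One cell of the factorial design. Group 1 is always standard normal;
#' group 2 is skew-normal moment-matched to mean `delta`, SD `sigma`, and
#' slant `alpha`; both groups have `n` observations.
#'
#' @param delta True mean difference (group-2 mean minus group-1 mean).
#' @param sigma Group-2 target SD (> 0).
#' @param alpha Group-2 slant.
#' @param n Per-group sample size (>= 2).
#' @return A list of class `"ovl_condition"` carrying the four cell
#'   parameters and the group-2 [sn_spec()].
#' @export
condition <- function(delta, sigma, alpha, n) {
  if (n < 2) stop("'n' must be >= 2", call. = FALSE)
  structure(list(delta = as.numeric(delta), sigma = as.numeric(sigma),
                 alpha = as.numeric(alpha), n = as.integer(n),
                 spec2 = sn_params_from_moments(delta, sigma, alpha)),
            class = "ovl_condition")
}

#' Population Cohen's d for a condition
#'
#' The population counterpart of the pooled-SD standardiser at equal group
#' sizes: `-delta / sqrt((1 + sigma^2) / 2)` under the group-1-minus-group-2
#' sign convention. The moment-matching parameterisation guarantees group 2
#' has mean `delta` and SD `sigma` for every slant, so the value does not
#' depend on `alpha`.
#'
#' @param cond An [condition()] object.
#' @return A single number.
#' @export
true_d <- function(cond) {
  stopifnot(inherits(cond, "ovl_condition"))
  -cond$delta / sqrt((1 + cond$sigma^2) / 2)
}

#' Population probability of superiority for a condition
#'
#' `P(Y2 > Y1)` with `Y1` standard normal and `Y2` the condition's
#' skew-normal, computed by quadrature of `integral Phi(y) f2(y) dy`, then
#' folded to `max(p, 1 - p)` to match the direction-free estimator
#' `pnorm(|d|/sqrt(2))`.
#'
#' @param cond An [condition()] object.
#' @param folded Logical; return `max(p, 1-p)` (default) or the raw
#'   `P(Y2 > Y1)`.
#' @return A probability.
#' @export
true_cles <- function(cond, folded = TRUE) {
  stopifnot(inherits(cond, "ovl_condition"))
  p <- stats::integrate(function(y) stats::pnorm(y) * sn_pdf(y, cond$spec2),
                        -Inf, Inf, rel.tol = 1e-10)$value
  p <- min(max(p, 0), 1)
  if (folded) max(p, 1 - p) else p
}

#' Population overlap for a condition
#'
#' The shared area `integral min(f1, f2)` between the standard normal
#' density and the condition's skew-normal density, by adaptive quadrature
#' over a range covering all but a negligible tail mass of both densities.
#' This single quantity is the estimation target for both the parametric
#' and the nonparametric overlap indices.
#'
#' @param cond An [condition()] object.
#' @return A probability in `(0, 1]`.
#' @export
true_overlap <- function(cond) {
  stopifnot(inherits(cond, "ovl_condition"))
  s_max <- max(1, cond$sigma)
  lo <- min(0, cond$delta) - 10 * s_max
  hi <- max(0, cond$delta) + 10 * s_max
  f <- function(y) pmin(stats::dnorm(y), sn_pdf(y, cond$spec2))
  v <- stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 1e-10,
                        subdivisions = 2000L)$value
  min(max(v, 0), 1)
}

#' True parameter values for every index in a condition
#'
#' @param cond An [condition()] object.
#' @param theta_cles_rule `"true_probability"` (default): the folded
#'   population probability of superiority; `"transform_of_theta_d"`:
#'   `pnorm(|theta_d|/sqrt(2))`, the normal-theory transform of the
#'   population d.
#' @return Named numeric vector `c(theta_d, theta_cles, theta_overlap)`.
#'   The overlap value is the shared target of the parametric and
#'   nonparametric overlap indices.
#' @export
true_values <- function(cond,
                        theta_cles_rule = c("true_probability",
                                            "transform_of_theta_d")) {
  theta_cles_rule <- match.arg(theta_cles_rule)
  td <- true_d(cond)
  tc <- switch(theta_cles_rule,
               true_probability = true_cles(cond),
               transform_of_theta_d = cles_from_d(td))
  c(theta_d = td, theta_cles = tc, theta_overlap = true_overlap(cond))
}
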