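# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: plain dnorm/pnorm quadrature, double loops, and
# the erf-based density formula.

# probability of superiority by brute-force enumeration; ties dropped
brute_cles <- function(y1, y2) {
  n1 <- 0L
  n0 <- 0L
  for (a in y1) {
    for (b in y2) {
      if (a > b) n1 <- n1 + 1L else if (a < b) n0 <- n0 + 1L
    }
  }
  n1 / (n1 + n0)
}

# overlap of N(0,1) and N(delta, sigma^2) by direct quadrature of dnorm
normal_overlap <- function(delta, sigma) {
  stats::integrate(function(x) pmin(stats::dnorm(x),
                                    stats::dnorm(x, delta, sigma)),
                   min(0, delta) - 12 * max(1, sigma),
                   max(0, delta) + 12 * max(1, sigma),
                   subdivisions = 2000L, rel.tol = 1e-10)$value
}

# skew-normal density written straight from the erf form, using pracma's
# independent erf implementation when available
erf_sn_pdf <- function(y, xi, omega, alpha) {
  skip_if_not_installed("pracma")
  z <- (y - xi) / omega
  1 / (omega * sqrt(2 * pi)) * exp(-z^2 / 2) *
    (1 + pracma::erf(alpha * z / sqrt(2)))
}

sample_skewness <- function(y) {
  mean((y - mean(y))^3) / (mean((y - mean(y))^2))^1.5
}

# the eight (delta, sigma, alpha) scenario cells of the default design
scenario_cells <- expand.grid(delta = c(0, 2), sigma = c(1, 5),
                              alpha = c(0, 10))
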