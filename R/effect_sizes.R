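#' Cohen's d with pooled standard deviation
#'
#' Standardised mean difference `(mean(y1) - mean(y2)) / s_p`, where
#' `s_p^2 = ((n1-1)*s1^2 + (n2-1)*s2^2) / (n1+n2-2)` uses the unbiased
#' sample variances. The sign convention is group 1 minus group 2.
#'
#' @param y1,y2 Numeric vectors, each of length >= 2.
#' @return A single number (unbounded, negative when group 2 has the larger
#'   mean).
#' @examples
#' cohen_d(c(0, 1, 2), c(1, 2, 3))  # -1
#' @export
cohen_d <- function(y1, y2) {
  n1 <- length(y1); n2 <- length(y2)
  if (n1 < 2L || n2 < 2L) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  sp2 <- ((n1 - 1) * stats::var(y1) + (n2 - 1) * stats::var(y2)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) {
    stop("degenerate sample: pooled standard deviation is zero",
         call. = FALSE)
  }
  (mean(y1) - mean(y2)) / sqrt(sp2)
}

#' Common Language Effect Size from ordered pairs
#'
#' The empirical probability of superiority: over all `n1 * n2` ordered
#' pairs `(y1_i, y2_j)`, `CL = N1 / (N1 + N0)` where `N1` counts pairs with
#' the first observation strictly greater and `N0` pairs with it strictly
#' smaller. Tied pairs contribute to neither count.
#'
#' @param y1,y2 Numeric vectors (length >= 1 each).
#' @return A probability in `[0, 1]`.
#' @examples
#' cles_empirical(c(3, 4), c(1, 2))  # 1
#' cles_empirical(c(1, 2), c(1, 2))  # 0.5 (two ties dropped)
#' @export
cles_empirical <- function(y1, y2) {
  if (length(y1) < 1L || length(y2) < 1L) {
    stop("both groups need at least 1 observation", call. = FALSE)
  }
  s2 <- sort(y2)
  # counts of y2 strictly below / at-or-below each y1 value
  n_lt  <- findInterval(y1, s2, left.open = TRUE)
  n_leq <- findInterval(y1, s2)
  N1 <- sum(n_lt)                        # y1 > y2
  N0 <- sum(length(y2) - n_leq)          # y1 < y2
  if (N1 + N0 == 0) {
    stop("undefined statistic: every ordered pair is tied", call. = FALSE)
  }
  N1 / (N1 + N0)
}

#' Common Language Effect Size as a transform of Cohen's d
#'
#' Under normality and equal variances the probability of superiority is a
#' deterministic function of the standardised mean difference:
#' `CL = pnorm(|d| / sqrt(2))`. The fold through `|d|` makes the value
#' direction-free, so the result lies in `[0.5, 1]`.
#'
#' @param d Cohen's d (finite).
#' @return A probability in `[0.5, 1]`.
#' @examples
#' cles_from_d(0)  # 0.5
#' cles_from_d(2)  # pnorm(sqrt(2))
#' @export
cles_from_d <- function(d) {
  if (!is.numeric(d) || anyNA(d) || any(!is.finite(d))) {
    stop("'d' must be finite", call. = FALSE)
  }
  stats::pnorm(abs(d) / sqrt(2))
}

#' Parametric overlap coefficient from Cohen's d
#'
#' The overlapping area of two equal-variance normal densities separated by
#' `d` pooled standard deviations: `eta_p = 2 * pnorm(-|d| / 2)`. Equal
#' means give complete overlap (1); the value decays to 0 as `|d|` grows.
#'
#' @param d Cohen's d (finite).
#' @return A probability in `(0, 1]`.
#' @examples
#' overlap_parametric(0)  # 1
#' overlap_parametric(2)  # 2 * pnorm(-1)
#' @export
overlap_parametric <- function(d) {
  if (!is.numeric(d) || anyNA(d) || any(!is.finite(d))) {
    stop("'d' must be finite", call. = FALSE)
  }
  2 * stats::pnorm(-abs(d) / 2)
}

#' Kernel density settings for the nonparametric overlap
#'
#' @param kernel Kernel name passed to [stats::density()] (default
#'   `"gaussian"`).
#' @param bandwidth_rule Bandwidth selector: `"nrd0"` (Silverman's rule of
#'   thumb, `0.9 * min(sd, IQR/1.34) * n^(-1/5)`), `"nrd"`, `"SJ"`, or
#'   `"ucv"`.
#' @param grid_points Number of shared grid points (>= 64; default 1024).
#' @param grid_cut Grid extension beyond the pooled data range, in units of
#'   the larger bandwidth (default 3).
#' @return A list of class `"kde_config"`.
#' @export
kde_config <- function(kernel = "gaussian", bandwidth_rule = "nrd0",
                       grid_points = 1024L, grid_cut = 3) {
  bandwidth_rule <- match.arg(bandwidth_rule, c("nrd0", "nrd", "SJ", "ucv"))
  if (grid_points < 64L) stop("'grid_points' must be >= 64", call. = FALSE)
  if (grid_cut < 0) stop("'grid_cut' must be >= 0", call. = FALSE)
  structure(list(kernel = kernel, bandwidth_rule = bandwidth_rule,
                 grid_points = as.integer(grid_points),
                 grid_cut = as.numeric(grid_cut)),
            class = "kde_config")
}

bw_select <- function(y, rule) {
  if (stats::sd(y) == 0) {
    # zero spread: the bandwidth rules would fall back to an arbitrary
    # positive width, silently hiding a degenerate sample
    stop("degenerate sample: kernel bandwidth is zero", call. = FALSE)
  }
  bw <- switch(rule,
               nrd0 = stats::bw.nrd0(y),
               nrd  = stats::bw.nrd(y),
               SJ   = stats::bw.SJ(y),
               ucv  = suppressWarnings(stats::bw.ucv(y)))
  if (!is.finite(bw) || bw <= 0) {
    stop("degenerate sample: kernel bandwidth is zero", call. = FALSE)
  }
  bw
}

# trapezoidal rule on an equispaced grid
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Nonparametric overlapping index from kernel density estimates
#'
#' Estimates `eta = integral of min(f1, f2)`, the shared area under the two
#' group densities. Both densities are kernel-estimated on one shared
#' equispaced grid spanning the union of the samples extended by
#' `grid_cut` bandwidths, renormalised to unit mass on that grid, and the
#' pointwise minimum is integrated by the trapezoidal rule. Values range
#' from 0 (disjoint supports) to 1 (identical distributions).
#'
#' @param y1,y2 Numeric vectors, each of length >= 2 with nonzero spread.
#' @param cfg A [kde_config()] object.
#' @return A number in `[0, 1]`.
#' @examples
#' set.seed(1)
#' overlap_nonparametric(rnorm(200), rnorm(200, 2))
#' @export
overlap_nonparametric <- function(y1, y2, cfg = kde_config()) {
  stopifnot(inherits(cfg, "kde_config"))
  if (length(y1) < 2L || length(y2) < 2L) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  bw1 <- bw_select(y1, cfg$bandwidth_rule)
  bw2 <- bw_select(y2, cfg$bandwidth_rule)
  pad <- cfg$grid_cut * max(bw1, bw2)
  lo <- min(y1, y2) - pad
  hi <- max(y1, y2) + pad
  f1 <- stats::density(y1, bw = bw1, kernel = cfg$kernel,
                       from = lo, to = hi, n = cfg$grid_points)
  f2 <- stats::density(y2, bw = bw2, kernel = cfg$kernel,
                       from = lo, to = hi, n = cfg$grid_points)
  d1 <- f1$y / trapz(f1$x, f1$y)
  d2 <- f2$y / trapz(f2$x, f2$y)
  min(max(trapz(f1$x, pmin(d1, d2)), 0), 1)
}
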