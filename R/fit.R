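#' Fit the four effect-size indices to a two-group sample
#'
#' The front door of the package for real data: computes Cohen's d, the
#' Common Language Effect Size, the parametric overlap `2*pnorm(-|d|/2)`,
#' and the kernel-based nonparametric overlap on one pair of samples,
#' together with 95% confidence intervals (noncentral-t inversion for d,
#' endpoint transformation for CLES and the parametric overlap, percentile
#' bootstrap for the kernel overlap).
#'
#' @param x For the default method, the group-1 numeric vector. For the
#'   formula method, a two-sided formula `response ~ group` where `group`
#'   has exactly two levels (the first level is group 1).
#' @param ... Passed between methods.
#' @return An object of class `"overlap_es"`; see [print.overlap_es()],
#'   [summary.overlap_es()], [confint.overlap_es()], [plot.overlap_es()].
#' @examples
#' set.seed(42)
#' fit <- overlap_es(rnorm(60), rnorm(60, 1), n_boot = 200)
#' fit
#' confint(fit)
#' @export
overlap_es <- function(x, ...) UseMethod("overlap_es")

#' @rdname overlap_es
#' @param data A data frame for the formula method.
#' @export
overlap_es.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  if (ncol(mf) != 2L) {
    stop("formula must be of the form response ~ group", call. = FALSE)
  }
  grp <- factor(mf[[2L]])
  if (nlevels(grp) != 2L) {
    stop("grouping variable must have exactly two levels", call. = FALSE)
  }
  y <- mf[[1L]]
  out <- overlap_es.default(y[grp == levels(grp)[1L]],
                            y[grp == levels(grp)[2L]], ...)
  out$call <- match.call()
  out$group_labels <- levels(grp)
  out
}

#' @rdname overlap_es
#' @param y Group-2 numeric vector (default method).
#' @param level Nominal confidence level, default 0.95.
#' @param cles_estimator `"from_d"` (default; `pnorm(|d|/sqrt(2))`, kept
#'   coherent with the transformed interval) or `"empirical"` (ordered-pair
#'   count).
#' @param kde A [kde_config()] for the nonparametric overlap.
#' @param n_boot Bootstrap resamples for the overlap interval.
#' @param ci Logical; compute confidence intervals (default `TRUE`).
#' @param seed Optional seed making the bootstrap reproducible.
#' @export
overlap_es.default <- function(x, y, level = 0.95,
                               cles_estimator = c("from_d", "empirical"),
                               kde = kde_config(), n_boot = 1000L,
                               ci = TRUE, seed = NULL, ...) {
  cles_estimator <- match.arg(cles_estimator)
  d <- cohen_d(x, y)
  cl <- if (cles_estimator == "from_d") cles_from_d(d) else
    cles_empirical(x, y)
  est <- c(d = d, cles = cl, eta_p = overlap_parametric(d),
           eta = overlap_nonparametric(x, y, kde))
  intervals <- NULL
  if (ci) {
    ci_d <- ci_d_noncentral(x, y, level)
    intervals <- list(
      d     = ci_d,
      cles  = ci_transform_monotone(ci_d, "cles"),
      eta_p = ci_transform_monotone(ci_d, "eta_p"),
      eta   = ci_eta_bootstrap(x, y, n_boot = n_boot, kde = kde,
                               level = level, seed = seed))
  }
  structure(list(estimates = est, intervals = intervals, level = level,
                 n1 = length(x), n2 = length(y), y1 = x, y2 = y,
                 cles_estimator = cles_estimator, kde = kde,
                 group_labels = c("group1", "group2"),
                 call = match.call()),
            class = "overlap_es")
}

#' @export
print.overlap_es <- function(x, digits = 4, ...) {
  cat("Two-group effect sizes (n1 =", x$n1, ", n2 =", x$n2, ")\n")
  print(round(x$estimates, digits))
  invisible(x)
}

#' @export
coef.overlap_es <- function(object, ...) object$estimates

#' Confidence intervals for a fitted effect-size object
#'
#' @param object An [overlap_es()] fit with `ci = TRUE`.
#' @param parm Indices to extract (default all four).
#' @param level Ignored; the level is fixed at fit time.
#' @param ... Unused.
#' @return A matrix with columns `lower`, `upper` and one row per index.
#' @export
confint.overlap_es <- function(object, parm = names(object$estimates),
                               level = NULL, ...) {
  if (is.null(object$intervals)) {
    stop("fit was computed with ci = FALSE", call. = FALSE)
  }
  parm <- match.arg(parm, names(object$estimates), several.ok = TRUE)
  out <- t(vapply(object$intervals[parm],
                  function(i) c(i$lower, i$upper), numeric(2)))
  colnames(out) <- c("lower", "upper")
  out
}

#' @export
summary.overlap_es <- function(object, ...) {
  tab <- data.frame(estimate = object$estimates)
  if (!is.null(object$intervals)) {
    ci <- confint(object)
    tab$lower <- ci[, "lower"]
    tab$upper <- ci[, "upper"]
  }
  structure(list(table = tab, level = object$level, n1 = object$n1,
                 n2 = object$n2, cles_estimator = object$cles_estimator),
            class = "summary.overlap_es")
}

#' @export
print.summary.overlap_es <- function(x, digits = 4, ...) {
  cat(sprintf("Two-group effect sizes (n1 = %d, n2 = %d, CLES: %s)\n",
              x$n1, x$n2, x$cles_estimator))
  if (ncol(x$table) > 1) {
    cat(sprintf("%.0f%% confidence intervals\n", 100 * x$level))
  }
  print(round(x$table, digits))
  invisible(x)
}

#' Density plot of the two groups with the shared area shaded
#'
#' Draws the two kernel density estimates on the shared grid used by the
#' overlap computation and shades their pointwise minimum, whose area is
#' the nonparametric overlap estimate.
#'
#' @param x An [overlap_es()] fit.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.overlap_es <- function(x, ...) {
  cfg <- x$kde
  bw1 <- bw_select(x$y1, cfg$bandwidth_rule)
  bw2 <- bw_select(x$y2, cfg$bandwidth_rule)
  pad <- cfg$grid_cut * max(bw1, bw2)
  lo <- min(x$y1, x$y2) - pad
  hi <- max(x$y1, x$y2) + pad
  f1 <- stats::density(x$y1, bw = bw1, kernel = cfg$kernel,
                       from = lo, to = hi, n = cfg$grid_points)
  f2 <- stats::density(x$y2, bw = bw2, kernel = cfg$kernel,
                       from = lo, to = hi, n = cfg$grid_points)
  ylim <- c(0, max(f1$y, f2$y))
  graphics::plot(f1$x, f1$y, type = "n", ylim = ylim,
                 xlab = "value", ylab = "density", ...)
  shared <- pmin(f1$y, f2$y)
  graphics::polygon(c(f1$x, rev(f1$x)), c(shared, numeric(length(shared))),
                    col = "grey80", border = NA)
  graphics::lines(f1$x, f1$y, col = "black")
  graphics::lines(f2$x, f2$y, col = "red")
  graphics::legend("topright", bty = "n", col = c("black", "red"), lty = 1,
                   legend = x$group_labels)
  graphics::mtext(sprintf("overlap = %.3f", x$estimates[["eta"]]),
                  side = 3, line = 0.2, cex = 0.9)
  invisible(x)
}
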