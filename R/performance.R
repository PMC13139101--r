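#' Relative mean bias
#'
#' Average proportional deviation of an estimator from its population
#' value: `mean((est - theta) / theta)`. Values within +/-0.10 are the
#' conventional acceptability band. When `theta` is exactly zero, a small
#' constant `eps` replaces it in the denominator so the ratio stays
#' defined; the resulting values are large by construction and should be
#' read alongside the raw mean bias.
#'
#' @param estimates Nonempty numeric vector of replicate estimates.
#' @param theta True parameter value (finite).
#' @param eps Substitute denominator when `theta == 0` (default `1e-6`).
#' @return A single number.
#' @examples
#' rmb(c(1.1, 0.9), 1)  # 0
#' @export
rmb <- function(estimates, theta, eps = 1e-6) {
  if (length(estimates) == 0) stop("'estimates' is empty", call. = FALSE)
  stopifnot(is.finite(theta))
  denom <- if (theta == 0) eps else theta
  mean((estimates - theta) / denom)
}

#' Normalised root mean square error
#'
#' `sqrt(mean((est - theta)^2))` divided by the empirical range
#' `max(est) - min(est)`, giving a scale-free dispersion-and-bias summary.
#' A zero range with zero RMSE (perfect estimation) returns 0; a zero range
#' with nonzero RMSE is undefined and returns `NA`.
#'
#' @inheritParams rmb
#' @return A nonnegative number, or `NA` when undefined.
#' @examples
#' nrmse(c(0, 2), 1)  # 0.5
#' @export
nrmse <- function(estimates, theta) {
  if (length(estimates) == 0) stop("'estimates' is empty", call. = FALSE)
  rmse <- sqrt(mean((estimates - theta)^2))
  rng <- max(estimates) - min(estimates)
  if (rng == 0) {
    if (rmse == 0) 0 else NA_real_
  } else {
    rmse / rng
  }
}

#' Empirical interval coverage
#'
#' Fraction of replicates whose confidence interval contains the true
#' value (closed endpoints).
#'
#' @param lower,upper Numeric vectors of interval bounds, same length.
#' @param theta True parameter value.
#' @return A proportion in `[0, 1]`.
#' @examples
#' coverage(c(0, 0, 1.2), c(2, 0.5, 3), theta = 1)  # 2/3
#' @export
coverage <- function(lower, upper, theta) {
  if (length(lower) == 0) stop("empty interval list", call. = FALSE)
  stopifnot(length(lower) == length(upper))
  mean(lower <= theta & theta <= upper)
}

#' Pairwise Pearson correlations among the four indices
#'
#' Correlates the replicate-level estimates pooled across every condition
#' in the table. Two matrices are produced: `signed`, the plain Pearson
#' correlations of the raw columns (d keeps its sign), and `magnitude`,
#' the absolute correlations computed after folding d to `|d|` — the
#' direction-free scale on which the three d-derived indices live.
#'
#' @param results An `ovl_results` table (or any data frame with columns
#'   `d`, `cles`, `eta_p`, `eta`).
#' @return A list of class `"ovl_cor"` with 4x4 matrices `signed` and
#'   `magnitude`.
#' @export
correlation_matrix <- function(results) {
  cols <- c("d", "cles", "eta_p", "eta")
  stopifnot(all(cols %in% names(results)), nrow(results) >= 3)
  raw <- as.matrix(results[cols])
  if (any(apply(raw, 2, stats::sd) == 0)) {
    stop("undefined correlation: an index has zero variance",
         call. = FALSE)
  }
  folded <- raw
  folded[, "d"] <- abs(folded[, "d"])
  structure(list(signed = stats::cor(raw),
                 magnitude = abs(stats::cor(folded))),
            class = "ovl_cor")
}

#' @export
print.ovl_cor <- function(x, digits = 3, ...) {
  cat("Pooled replicate-level Pearson correlations\n\nsigned:\n")
  print(round(x$signed, digits))
  cat("\nmagnitude (d folded to |d|):\n")
  print(round(x$magnitude, digits))
  invisible(x)
}

# per-index column mapping: estimate column, interval columns, which theta
index_map <- list(
  d     = list(est = "d",     lo = "d_lo",    hi = "d_hi",
               theta = "theta_d"),
  cles  = list(est = "cles",  lo = "cles_lo", hi = "cles_hi",
               theta = "theta_cles"),
  eta_p = list(est = "eta_p", lo = "etap_lo", hi = "etap_hi",
               theta = "theta_overlap"),
  eta   = list(est = "eta",   lo = "eta_lo",  hi = "eta_hi",
               theta = "theta_overlap")
)

#' Per-condition performance summary
#'
#' Computes, for every condition and every index, the relative mean bias,
#' the raw mean bias, the normalised RMSE, and (when intervals were
#' computed) the empirical coverage, each against the index's own
#' population target: the population d for d, the folded probability of
#' superiority for CLES (rule configurable), and the true density overlap
#' for both overlap indices.
#'
#' @param results An `ovl_results` table from [run_grid()].
#' @param truths Optional data frame of per-condition true values (columns
#'   `delta`, `sigma`, `alpha`, `n`, `theta_d`, `theta_cles`,
#'   `theta_overlap`); defaults to the table's `"truths"` attribute, or is
#'   recomputed if absent.
#' @return A data frame with columns `delta`, `sigma`, `alpha`, `n`,
#'   `index`, `theta`, `rmb`, `raw_bias`, `nrmse`, `coverage`, `redraws`.
#' @export
summarize_conditions <- function(results, truths = NULL) {
  if (is.null(truths)) truths <- attr(results, "truths")
  cfg <- attr(results, "config")
  cells <- unique(as.data.frame(
    results[c("delta", "sigma", "alpha", "n")]))
  if (is.null(truths)) {
    rule <- if (is.null(cfg)) "true_probability" else cfg$theta_cles_rule
    truths <- cells
    tv <- t(vapply(seq_len(nrow(cells)), function(i) {
      true_values(condition(cells$delta[i], cells$sigma[i],
                            cells$alpha[i], cells$n[i]), rule)
    }, numeric(3)))
    truths[, c("theta_d", "theta_cles", "theta_overlap")] <- tv
  }
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    rownames(cell) <- NULL
    sel <- results$delta == cell$delta & results$sigma == cell$sigma &
      results$alpha == cell$alpha & results$n == cell$n
    sub <- results[sel, , drop = FALSE]
    tr <- truths[truths$delta == cell$delta & truths$sigma == cell$sigma &
                   truths$alpha == cell$alpha & truths$n == cell$n, ,
                 drop = FALSE]
    rows <- lapply(names(index_map), function(ix) {
      m <- index_map[[ix]]
      theta <- tr[[m$theta]][1]
      est <- sub[[m$est]]
      cov <- if (all(is.na(sub[[m$lo]]))) NA_real_ else
        coverage(sub[[m$lo]], sub[[m$hi]], theta)
      data.frame(cell, index = ix, theta = theta,
                 rmb = rmb(est, theta),
                 raw_bias = mean(est) - theta,
                 nrmse = nrmse(est, theta), coverage = cov,
                 redraws = if ("redraws" %in% names(tr))
                   tr$redraws[1] else NA_integer_)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write the per-condition summary to CSV
#'
#' @param summary_df Output of [summarize_conditions()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_summary_csv <- function(summary_df, path) {
  utils::write.csv(summary_df, path, row.names = FALSE)
  invisible(path)
}
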