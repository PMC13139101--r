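#' Simulation run configuration
#'
#' Collects every setting of a Monte-Carlo study: the factorial grid, the
#' replicate count, seeding, the interval level, and kernel / bootstrap /
#' estimator options. The defaults reproduce the full study design: group-2
#' mean difference `delta` in {0, 2}, target SD `sigma` in {1, 5}, slant
#' `alpha` in {0, 10}, per-group sizes {10, 50, 100, 300, 500, 1000} — 8
#' scenarios crossed with 6 sample sizes, 48 conditions — at 2000 replicate
#' pairs per condition.
#'
#' @param deltas,sigmas,alphas,ns Numeric vectors defining the grid.
#' @param n_reps Replicate sample pairs per condition (default 2000).
#' @param master_seed Integer master seed; every replicate's seed is derived
#'   deterministically from it and the cell parameters, so results are
#'   reproducible and independent of the order conditions are run in.
#' @param ci_level Nominal interval coverage (default 0.95).
#' @param compute_intervals Logical; skip all interval construction when
#'   `FALSE` (point estimates only — much faster for bias/correlation
#'   summaries).
#' @param n_boot Bootstrap resamples for the overlap interval (default
#'   1000).
#' @param boot_eta_ci Logical; when `FALSE` the percentile-bootstrap
#'   interval for the nonparametric overlap is skipped (its columns stay
#'   `NA`) while the analytic intervals for the other three indices are
#'   still computed. Useful when only d-family coverage is of interest.
#' @param kde A [kde_config()].
#' @param cles_estimator `"from_d"` (default) or `"empirical"`; which CLES
#'   point estimate is recorded per replicate.
#' @param theta_cles_rule Which population value CLES is judged against in
#'   summaries; see [true_values()].
#' @param widen_etap_at_zero Logical; widen the transformed parametric
#'   overlap interval to include 1 when the d interval straddles zero
#'   (default `FALSE`: literal endpoint rule).
#' @param verbose Logical; print per-condition progress.
#' @return A list of class `"run_config"`.
#' @examples
#' cfg <- run_config(n_reps = 10, master_seed = 1)
#' nrow(condition_grid(cfg))  # 48
#' @export
run_config <- function(deltas = c(0, 2), sigmas = c(1, 5),
                       alphas = c(0, 10),
                       ns = c(10, 50, 100, 300, 500, 1000),
                       n_reps = 2000L, master_seed = 1L, ci_level = 0.95,
                       compute_intervals = TRUE, n_boot = 1000L,
                       boot_eta_ci = TRUE, kde = kde_config(),
                       cles_estimator = c("from_d", "empirical"),
                       theta_cles_rule = c("true_probability",
                                           "transform_of_theta_d"),
                       widen_etap_at_zero = FALSE, verbose = FALSE) {
  stopifnot(n_reps >= 1, ci_level > 0, ci_level < 1, all(ns >= 2),
            all(sigmas > 0))
  structure(list(
    deltas = as.numeric(deltas), sigmas = as.numeric(sigmas),
    alphas = as.numeric(alphas), ns = as.integer(ns),
    n_reps = as.integer(n_reps), master_seed = as.integer(master_seed),
    ci_level = ci_level, compute_intervals = isTRUE(compute_intervals),
    n_boot = as.integer(n_boot), boot_eta_ci = isTRUE(boot_eta_ci),
    kde = kde,
    cles_estimator = match.arg(cles_estimator),
    theta_cles_rule = match.arg(theta_cles_rule),
    widen_etap_at_zero = isTRUE(widen_etap_at_zero),
    verbose = isTRUE(verbose)),
    class = "run_config")
}

#' Read a run configuration from a JSON or YAML file
#'
#' Any field of [run_config()] may appear in the file; missing fields keep
#' their defaults. The `kde` field, if present, is a mapping with
#' [kde_config()] fields.
#'
#' @param path Path to a `.json`, `.yaml`, or `.yml` file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml  = yaml::read_yaml(path),
                stop("config file must be .json, .yaml, or .yml",
                     call. = FALSE))
  if (!is.null(raw$kde)) raw$kde <- do.call(kde_config, raw$kde)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

#' Enumerate the factorial grid of a configuration
#'
#' @param cfg A [run_config()].
#' @return A data frame with one row per condition and columns `delta`,
#'   `sigma`, `alpha`, `n`, ordered with `n` varying fastest.
#' @export
condition_grid <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  g <- expand.grid(n = cfg$ns, alpha = cfg$alphas, sigma = cfg$sigmas,
                   delta = cfg$deltas, KEEP.OUT.ATTRS = FALSE)
  g[, c("delta", "sigma", "alpha", "n")]
}

#' @export
print.run_config <- function(x, ...) {
  g <- condition_grid(x)
  cat(sprintf(
    "Simulation config: %d scenarios x %d sample sizes = %d conditions\n",
    length(x$deltas) * length(x$sigmas) * length(x$alphas),
    length(x$ns), nrow(g)))
  cat(sprintf("  %d replicates/condition, master seed %d, intervals: %s\n",
              x$n_reps, x$master_seed,
              if (x$compute_intervals) "on" else "off"))
  invisible(x)
}
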