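small_cfg <- function(...) {
  run_config(compute_intervals = FALSE, master_seed = 123, ...)
}

test_that("a condition run produces the contracted number of records", {
  cond <- condition(2, 5, 10, 10)
  out <- run_condition(cond, small_cfg(n_reps = 5))
  expect_equal(nrow(out), 5)
  expect_equal(out$rep, 1:5)
  expect_equal(length(unique(out$seed)), 5)
  expect_true(all(is.finite(out$d)))
  expect_true(all(out$cles >= 0 & out$cles <= 1))
  expect_true(all(out$eta_p >= 0 & out$eta_p <= 1))
  expect_true(all(out$eta >= 0 & out$eta <= 1))
})

test_that("the default grid enumerates 8 scenarios and 48 conditions", {
  cfg <- run_config()
  g <- condition_grid(cfg)
  expect_equal(nrow(g), 48)
  expect_equal(nrow(unique(g[c("delta", "sigma", "alpha")])), 8)
  expect_equal(cfg$n_reps, 2000L)
})

test_that("a reduced grid yields conditions x replicates rows", {
  res <- run_grid(small_cfg(ns = 10, n_reps = 10))
  expect_equal(nrow(res), 80)  # 8 scenarios x 10 replicates
  expect_s3_class(res, "ovl_results")
  tr <- attr(res, "truths")
  expect_equal(nrow(tr), 8)
  expect_true(all(is.finite(tr$theta_overlap)))
})

test_that("runs are bit-identical and order-independent under one seed", {
  cfg <- small_cfg(ns = c(10, 20), n_reps = 4)
  r1 <- run_grid(cfg)
  r2 <- run_grid(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # permuting the grid must not change any replicate's values
  cfg_rev <- small_cfg(ns = c(20, 10), n_reps = 4)
  r3 <- run_grid(cfg_rev)
  key <- function(d) d[order(d$delta, d$sigma, d$alpha, d$n, d$rep), ]
  a <- key(as.data.frame(r1))
  b <- key(as.data.frame(r3))
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, ignore_attr = TRUE)
  # a single condition rerun in isolation reproduces its grid rows
  solo <- run_condition(condition(2, 5, 10, 20), cfg)
  from_grid <- subset(as.data.frame(r1),
                      delta == 2 & sigma == 5 & alpha == 10 & n == 20)
  rownames(from_grid) <- NULL
  expect_equal(solo, from_grid, ignore_attr = TRUE)
})

test_that("null-condition d estimates center on zero", {
  out <- run_condition(condition(0, 1, 0, 200), small_cfg(n_reps = 200))
  # sd(d-hat) is about sqrt(2/n); 4 standard errors of the replicate mean
  expect_lt(abs(mean(out$d)), 4 * sqrt(2 / 200) / sqrt(200))
})

test_that("kernel overlap estimates track the analytic overlap at large n", {
  out <- run_condition(condition(2, 1, 0, 1000), small_cfg(n_reps = 100))
  expect_lt(abs(mean(out$eta) - 2 * pnorm(-1)), 0.02)
})

test_that("interval columns honour the interval switches", {
  cfg_full <- run_config(n_reps = 3, n_boot = 100, master_seed = 5)
  out <- run_condition(condition(2, 1, 0, 20), cfg_full)
  expect_true(all(is.finite(out$d_lo)) && all(is.finite(out$eta_hi)))
  expect_true(all(out$d_lo <= out$d_hi))
  expect_true(all(out$eta_lo <= out$eta_hi))
  expect_true(all(out$cles_lo >= 0 & out$cles_hi <= 1))

  cfg_no_boot <- run_config(n_reps = 3, boot_eta_ci = FALSE, master_seed = 5)
  out2 <- run_condition(condition(2, 1, 0, 20), cfg_no_boot)
  expect_true(all(is.na(out2$eta_lo)))
  expect_true(all(is.finite(out2$etap_lo)))
  # point estimates are unaffected by which intervals are computed
  expect_identical(out$d, out2$d)
  expect_identical(out$eta, out2$eta)
})

test_that("configurations round-trip through JSON and YAML files", {
  tmp_json <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(ns = c(10, 50), n_reps = 7, master_seed = 42,
                            cles_estimator = "empirical",
                            kde = list(grid_points = 256)),
                       tmp_json, auto_unbox = TRUE)
  cfg <- read_run_config(tmp_json)
  expect_equal(cfg$ns, c(10L, 50L))
  expect_equal(cfg$n_reps, 7L)
  expect_equal(cfg$cles_estimator, "empirical")
  expect_equal(cfg$kde$grid_points, 256L)

  tmp_yaml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("deltas: [0, 2]", "ns: [10]", "n_reps: 3",
               "master_seed: 9"), tmp_yaml)
  cfg2 <- read_run_config(tmp_yaml)
  expect_equal(cfg2$n_reps, 3L)
  expect_equal(nrow(condition_grid(cfg2)), 8)

  writeLines(c("bogus_field: 1"), tmp_yaml)
  expect_error(read_run_config(tmp_yaml), "unknown config fields")
})

test_that("replicate CSV export keeps the documented column set", {
  res <- run_grid(small_cfg(ns = 10, n_reps = 2))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(res, tmp)
  back <- read.csv(tmp)
  expect_equal(names(back),
               c("delta", "sigma", "alpha", "n", "rep", "d", "cles",
                 "eta_p", "eta", "d_lo", "d_hi", "cles_lo", "cles_hi",
                 "etap_lo", "etap_hi", "eta_lo", "eta_hi", "seed"))
  expect_equal(nrow(back), nrow(res))
})
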