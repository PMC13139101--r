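test_that("relative mean bias follows its definition and the eps rule", {
  expect_equal(rmb(c(1.1, 0.9), 1), 0)
  expect_equal(rmb(1.2, 1), 0.2)
  expect_equal(rmb(0.001, 0), 1000)  # theta = 0 replaced by 1e-6
  expect_error(rmb(numeric(0), 1), "empty")
})

test_that("normalised RMSE follows its definition", {
  expect_equal(nrmse(c(0, 2), 1), 0.5)
  expect_equal(nrmse(c(1, 1, 1), 1), 0)
  expect_equal(nrmse(c(1, 3), 1), sqrt(2) / 2)
  expect_true(is.na(nrmse(c(2, 2), 1)))  # zero range, nonzero error
  expect_error(nrmse(numeric(0), 1), "empty")
  # scale-free contract: joint shifts of estimates and theta cancel
  set.seed(2)
  est <- rnorm(50)
  expect_equal(nrmse(est, 0.3), nrmse(est + 10, 10.3))
})

test_that("coverage counts closed-endpoint containment", {
  lo <- c(rep(0, 19), 2)
  hi <- c(rep(2, 19), 3)
  expect_equal(coverage(lo, hi, 1), 0.95)
  expect_equal(coverage(c(2, 3), c(4, 5), 1), 0)
  expect_equal(coverage(0, 1, 1), 1)  # endpoint included
  expect_error(coverage(numeric(0), numeric(0), 1), "empty")
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(4)
  tab <- data.frame(d = rnorm(100))
  tab$cles <- pnorm(abs(tab$d) / sqrt(2))
  tab$eta_p <- 2 * pnorm(-abs(tab$d) / 2)
  tab$eta <- runif(100)
  cm <- correlation_matrix(tab)
  for (m in cm[c("signed", "magnitude")]) {
    expect_equal(unname(diag(m)), rep(1, 4))
    expect_equal(m, t(m))
    expect_true(all(m >= -1 & m <= 1))
  }
  # deterministic monotone transforms of |d| correlate near +/- 1
  expect_gt(cm$magnitude["cles", "eta_p"], 0.99)
  tab$eta <- rep(0.5, 100)
  expect_error(correlation_matrix(tab), "zero variance")
})

test_that("a perfect-estimator table summarises to zero bias, full coverage", {
  cells <- data.frame(delta = c(0, 2), sigma = 1, alpha = 0, n = 10)
  truths <- cbind(cells, theta_d = c(0, -2), theta_cles = c(0.5, 0.9),
                  theta_overlap = c(1, 0.3))
  tab <- do.call(rbind, lapply(1:2, function(i) {
    cell <- cells[i, ]
    rownames(cell) <- NULL
    data.frame(cell, rep = 1:5, d = truths$theta_d[i],
               cles = truths$theta_cles[i], eta_p = truths$theta_overlap[i],
               eta = truths$theta_overlap[i],
               d_lo = truths$theta_d[i] - 1, d_hi = truths$theta_d[i] + 1,
               cles_lo = 0, cles_hi = 1, etap_lo = 0, etap_hi = 1,
               eta_lo = 0, eta_hi = 1, seed = 1L)
  }))
  s <- summarize_conditions(tab, truths)
  expect_equal(nrow(s), 8)  # 2 conditions x 4 indices
  expect_true(all(s$rmb == 0))
  expect_true(all(s$raw_bias == 0))
  expect_true(all(s$nrmse == 0))
  expect_true(all(s$coverage == 1))
})

test_that("small-sample inflation of d matches the Hedges closed form", {
  out <- run_condition(condition(2, 1, 0, 10),
                       run_config(n_reps = 1000, compute_intervals = FALSE,
                                  master_seed = 271))
  # E[d-hat] = d / J(df) with J the Hedges correction factor
  df <- 18
  J <- exp(lgamma(df / 2) - log(sqrt(df / 2)) - lgamma((df - 1) / 2))
  expected_rmb <- 1 / J - 1  # about +0.044 regardless of d's sign
  expect_lt(abs(rmb(out$d, -2) - expected_rmb), 0.03)
})

test_that("grid summaries carry one row per condition and index", {
  res <- run_grid(run_config(ns = c(10, 50), n_reps = 20, n_boot = 100,
                             master_seed = 11, boot_eta_ci = FALSE))
  s <- summarize_conditions(res)
  expect_equal(nrow(s), 16 * 4)
  expect_true(all(s$index %in% c("d", "cles", "eta_p", "eta")))
  expect_true(all(is.finite(s$coverage[s$index == "d"])))
  expect_true(all(is.na(s$coverage[s$index == "eta"])))
  expect_true(all(s$nrmse >= 0, na.rm = TRUE))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_summary_csv(s, tmp)
  expect_equal(nrow(read.csv(tmp)), nrow(s))
})
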