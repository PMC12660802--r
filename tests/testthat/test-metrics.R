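test_that("error metrics reproduce hand-computed values", {
  expect_equal(unname(mse_rmse(c(1, 2, 3, 4), c(2, 2, 4, 4))["mse"]), 0.5)
  expect_equal(unname(mse_rmse(c(0, 0), c(1, 1))), c(1, 1))
  expect_equal(unname(mse_rmse(1:5, 1:5)), c(0, 0))
  expect_error(mse_rmse(1:3, 1:4), "equal lengths")
})

test_that("residual SNR matches its defining ratio and limits", {
  x <- c(1, -2, 3)
  expect_equal(snr_filtered(x, 0 * x), 0)        # error energy = signal
  expect_identical(snr_filtered(x, x), Inf)
  expect_error(snr_filtered(c(0, 0), c(1, 1)), "zero signal energy")
})

test_that("PSNR uses the absolute peak and scales correctly", {
  expect_equal(psnr(c(0, 1), c(0, 0)), 10 * log10(1 / 0.5))
  expect_identical(psnr(1:4, 1:4), Inf)
  set.seed(31)
  x <- rnorm(200); xh <- x + rnorm(200, 0, 0.1)
  for (c in c(0.5, 3, 100)) {
    expect_equal(psnr(c * x, c * xh), psnr(x, xh), tolerance = 1e-12)
  }
  # signed-max variant differs when the extreme sample is negative
  y <- c(-2, 1); yh <- c(-1, 1)
  expect_equal(psnr(y, yh, peak = "max"), 10 * log10(1 / 0.5))
})

test_that("PRD covers the identity, annihilation and doubling cases", {
  x <- c(0.3, -1, 2, 0.5)
  expect_equal(prd(x, x), 0)
  expect_equal(prd(x, 0 * x), 100)
  expect_equal(prd(x, 2 * x), 100)
  expect_error(prd(c(0, 0), c(1, 1)), "zero signal energy")
})

test_that("correlation matches hand computation and affine invariance", {
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  set.seed(32)
  x <- rnorm(100)
  expect_equal(pearson_r(x, 3 * x + 7), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 100)), "zero-variance")
})

test_that("heuristic SNR gives 20*log10(2) on a unit square wave", {
  x <- rep(c(0, 1), 500)
  expect_equal(snr_original_heuristic(x), 20 * log10(2))
  expect_equal(snr_original_heuristic(5 * x + 2),
               snr_original_heuristic(x))
  expect_error(snr_original_heuristic(rep(3, 10)), "constant signal")
})

test_that("distribution stats use population moments and type-7 quantiles", {
  set.seed(33)
  u <- runif(500000)
  s <- distribution_stats(u)
  expect_equal(unname(s["kurtosis_excess"]), -1.2, tolerance = 0.03)
  expect_equal(unname(s["skewness"]), 0, tolerance = 0.02)
  g <- rnorm(1000000)
  sg <- distribution_stats(g)
  expect_equal(unname(sg["kurtosis_excess"]), 0, tolerance = 0.05)
  expect_equal(unname(sg["skewness"]), 0, tolerance = 0.05)
  # symmetric data has zero skewness exactly
  expect_equal(unname(distribution_stats(c(-2, -1, 1, 2))["skewness"]), 0)
  # constant input: moment ratios are undefined sentinels
  sc <- distribution_stats(rep(1, 10))
  expect_true(is.nan(sc["kurtosis_excess"]) && is.nan(sc["skewness"]))
  expect_equal(unname(sc[c("iqr", "std_dev")]), c(0, 0))
})

test_that("distribution stats agree with e1071's population estimators", {
  skip_if_not_installed("e1071")
  set.seed(34)
  for (i in 1:5) {
    x <- rnorm(500) * rexp(500)
    s <- distribution_stats(x)
    expect_equal(unname(s["kurtosis_excess"]),
                 e1071::kurtosis(x, type = 1), tolerance = 1e-12)
    expect_equal(unname(s["skewness"]),
                 e1071::skewness(x, type = 1), tolerance = 1e-12)
  }
})

test_that("the full metric suite matches brute-force loop oracles", {
  set.seed(35)
  for (i in 1:50) {
    x <- rnorm(100, sd = runif(1, 0.1, 10))
    xh <- x + rnorm(100, sd = runif(1, 0.01, 5))
    r <- compute_all(x, xh)
    expect_lt(rel_err(r$mse, oracle_mse(x, xh)), 1e-12)
    expect_lt(rel_err(r$rmse, oracle_rmse(x, xh)), 1e-12)
    expect_lt(rel_err(r$psnr_db, oracle_psnr(x, xh)), 1e-12)
    expect_lt(rel_err(r$prd_pct, oracle_prd(x, xh)), 1e-12)
    expect_lt(rel_err(r$pearson_r, oracle_pearson(x, xh)), 1e-12)
    expect_lt(rel_err(r$snr_filtered_db, oracle_snr_filtered(x, xh)),
              1e-12)
    expect_lt(rel_err(r$snr_original_db, oracle_snr_original(x)), 1e-12)
    expect_lt(rel_err(r$kurtosis_excess + 3, oracle_kurtosis(xh) + 3),
              1e-12)
    expect_lt(rel_err(r$skewness, oracle_skewness(xh)), 1e-12)
    expect_lt(rel_err(r$iqr, oracle_iqr(xh)), 1e-12)
    expect_lt(rel_err(r$std_dev, oracle_pop_sd(xh)), 1e-12)
  }
})

test_that("SNR and PRD are algebraically locked together", {
  set.seed(36)
  for (i in 1:25) {
    x <- rnorm(64); xh <- x + rnorm(64, 0, runif(1, 0.01, 2))
    expect_equal(snr_filtered(x, xh), 40 - 20 * log10(prd(x, xh)),
                 tolerance = 1e-9)
  }
})

test_that("compute_all is internally consistent", {
  set.seed(37)
  x <- rnorm(512)
  r <- compute_all(x, x + rnorm(512, 0, 0.3))
  expect_lt(abs(r$rmse^2 - r$mse), 1e-12)
  ri <- compute_all(x, x)
  expect_equal(ri$prd_pct, 0)
  expect_equal(ri$pearson_r, 1)
  expect_identical(ri$psnr_db, Inf)
  # common rescaling leaves the scale-free metrics alone, scales mse by c^2
  r2 <- compute_all(2 * x, 2 * (x + 0.1))
  r1 <- compute_all(x, x + 0.1)
  expect_equal(r2$prd_pct, r1$prd_pct, tolerance = 1e-12)
  expect_equal(r2$snr_filtered_db, r1$snr_filtered_db, tolerance = 1e-12)
  expect_equal(r2$mse, 4 * r1$mse, tolerance = 1e-12)
})
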