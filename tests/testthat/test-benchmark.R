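test_that("study grids have the documented cardinalities", {
  g <- default_grids()
  expect_length(enumerate_grid(g$highpass), 10)
  expect_length(enumerate_grid(g$ewt), 40)
  expect_length(enumerate_grid(g$swt), 320)
})

test_that("grid enumeration is lexicographic and constraint-aware", {
  g <- grid_spec("highpass", order = 2:6, normalized = c(TRUE, FALSE))
  cfgs <- enumerate_grid(g)
  p1 <- attr(cfgs[[1]], "params"); p2 <- attr(cfgs[[2]], "params")
  expect_equal(p1$order, 2); expect_true(p1$normalized)
  expect_equal(p2$order, 2); expect_false(p2$normalized)
  expect_equal(attr(cfgs[[3]], "params")$order, 3)

  # SGS constraint polyorder < window drops invalid combinations
  gs <- grid_spec("sgs", window = c(5, 7), polyorder = c(3, 6))
  expect_length(enumerate_grid(gs), 3)

  expect_error(grid_spec("sgs"), "at least one axis")
  expect_error(grid_spec("sgs", window = integer(0)), "empty axis")
  expect_error(grid_spec("nosuch", a = 1), "unknown filter")
})

test_that("grid search ranks configurations sensibly", {
  pair <- test_segment_pair(seed = 81)

  single <- run_grid_search(list(pair),
                            grid_spec("swt", threshold_scale = 0.5))
  expect_equal(attr(single$best_config, "params")$threshold_scale, 0.5)

  # identity-equivalent (scale 0) wins on clean input
  clean_pair <- list(clean = pair$clean)
  gs <- run_grid_search(list(clean_pair),
                        grid_spec("swt", threshold_scale = c(0, 0.5)))
  expect_equal(attr(gs$best_config, "params")$threshold_scale, 0)

  # under 10 dB noise, shrinkage beats no shrinkage
  rec <- generate_ecg(duration_s = 30, seed = 82)
  pairs <- lapply(1:10, function(i) {
    noisy_rec <- add_awgn(rec, 10, seed = 200 + i)
    list(clean = extract_segment(rec, "II"),
         noisy = extract_segment(noisy_rec, "II"))
  })
  gs2 <- run_grid_search(pairs,
                         grid_spec("swt", wavelet = "rbio3.9", level = 5,
                                   threshold_scale = c(0, 0.5, 1.0)))
  expect_true(attr(gs2$best_config, "params")$threshold_scale %in%
                c(0.5, 1.0))
})

test_that("dataset evaluation is deterministic and honest about identity", {
  recs <- test_records()[1:2]
  idrep <- evaluate_dataset(recs, identity_config(),
                            noise_conditions = NA, seed = 1)
  expect_equal(nrow(idrep), 24)
  expect_true(all(idrep$prd_pct == 0))
  expect_equal(idrep$pearson_r, rep(1, 24), tolerance = 1e-12)

  r1 <- evaluate_dataset(recs, swt_config(), noise_conditions = 10,
                         seed = 5)
  r2 <- evaluate_dataset(recs, swt_config(), noise_conditions = 10,
                         seed = 5)
  expect_identical(r1, r2)
  r3 <- evaluate_dataset(recs, swt_config(), noise_conditions = 10,
                         seed = 6)
  expect_false(identical(r1$mse, r3$mse))
})

test_that("wavelet shrinkage beats the Chebyshev band-pass on clean data", {
  recs <- test_records()[1:5]
  swt <- evaluate_dataset(recs, swt_config(), noise_conditions = NA)
  chb <- evaluate_dataset(recs, cheby2_config(), noise_conditions = NA)
  expect_lt(median(swt$prd_pct), median(chb$prd_pct))
})

test_that("aggregation reproduces order statistics and their invariants", {
  df <- data.frame(record = "r", lead = "L", condition = "clean",
                   filter = "f", m = c(1, 2, 3))
  agg <- aggregate_reports(df)
  expect_equal(unname(unlist(agg[, c("min", "max", "mean", "median")])),
               c(1, 3, 2, 2))

  one <- aggregate_reports(df[1, ])
  expect_true(all(one$min == one$max & one$max == one$mean))

  # permutation invariance on a larger frame
  set.seed(83)
  big <- data.frame(record = "r", lead = rep(c("a", "b"), 25),
                    condition = rep(c("clean", "10dB"), each = 25),
                    filter = "f", m = rnorm(50), k = rexp(50))
  sort_tab <- function(a) {
    a <- as.data.frame(a)[order(a$metric, a$condition), ]
    rownames(a) <- NULL
    a
  }
  a1 <- sort_tab(aggregate_reports(big))
  a2 <- sort_tab(aggregate_reports(big[sample(nrow(big)), ]))
  expect_equal(a1, a2)
  expect_true(all(a1$min <= a1$median & a1$median <= a1$max))
  expect_true(all(a1$min <= a1$mean & a1$mean <= a1$max))
})

test_that("non-finite sentinels are excluded from aggregation", {
  df <- data.frame(record = "r", lead = "L", condition = "clean",
                   filter = "f", psnr_db = c(10, Inf, 20))
  agg <- aggregate_reports(df)
  expect_equal(agg$max, 20)
  expect_equal(agg$n_excluded, 1)
  expect_equal(agg$n, 2)
})

test_that("the comparison table summarises per filter and condition", {
  b <- benchmark_10db()
  cmp <- b$comparison
  expect_setequal(unique(cmp$filter), names(default_filter_set()))
  expect_true(all(c("mean_rmse", "median_psnr", "median_prd",
                    "mean_correlation") %in% names(cmp)))
  expect_true(all(is.finite(cmp$median_prd)))
})

test_that("pooled 10 dB medians order the filter families as expected", {
  cmp <- benchmark_10db()$comparison
  prd_of <- function(f) cmp$median_prd[cmp$filter == f]
  # shrinkage beats smoothing beats the causal scalar Kalman beats the
  # band-limited EWT reconstruction; delay-compensated MA also beats EWT
  expect_lt(prd_of("swt"), prd_of("sgs"))
  expect_lt(prd_of("sgs"), prd_of("kalman"))
  expect_lt(prd_of("kalman"), prd_of("ewt"))
  expect_lt(prd_of("ma"), prd_of("ewt"))
})

test_that("timing harness reports self-ratio 1 and EMD slowest family", {
  rec <- generate_ecg(duration_s = 20, seed = 84, n_leads = 1)
  seg <- extract_segment(rec, 1, start_s = 1, n_samples = 16384)
  tt <- time_filters(seg, list(notch = notch_config(),
                               swt = swt_config(),
                               emd = emd_config()),
                     repetitions = 3, baseline = "swt")
  expect_equal(tt$ratio_to_baseline[tt$filter == "swt"], 1)
  expect_gt(tt$ratio_to_baseline[tt$filter == "emd"],
            tt$ratio_to_baseline[tt$filter == "notch"])
  expect_true(all(tt$min_s >= 0))
  expect_error(time_filters(seg, list(swt = swt_config()),
                            repetitions = 2), "3 repetitions")
})

test_that("benchmark_run writes its declared artifacts", {
  out <- withr::local_tempdir()
  recs <- test_records()[1:2]
  b <- benchmark_run(recs, filters = list(swt = swt_config(),
                                          notch = notch_config()),
                     noise_conditions = c(NA, 10), seed = 3,
                     out_dir = out)
  expect_true(file.exists(file.path(out, "comparison.csv")))
  expect_true(file.exists(file.path(out, "summary_swt.csv")))
  expect_true(file.exists(file.path(out, "summary_notch.csv")))
  expect_true(file.exists(file.path(out, "reports.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_equal(nrow(b$reports), 2 * 2 * 12 * 2)
})
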