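test_that("generation is reproducible and has the requested shape", {
  r1 <- generate_ecg(duration_s = 26.5, fs = 1000, seed = 7)
  r2 <- generate_ecg(duration_s = 26.5, fs = 1000, seed = 7)
  expect_identical(r1$signals, r2$signals)
  expect_equal(ncol(r1$signals), 26500)
  expect_equal(nrow(r1$signals), 12)
  r3 <- generate_ecg(duration_s = 26.5, fs = 1000, seed = 8)
  expect_false(identical(r1$signals, r3$signals))
  expect_error(generate_ecg(duration_s = -1), "positive")
})

test_that("clean leads sit in the clinical heuristic-SNR envelope", {
  for (seed in c(5, 17, 29)) {
    rec <- generate_ecg(duration_s = 30, seed = seed)
    snrs <- vapply(rec$lead_names, function(l) {
      snr_original_heuristic(extract_segment(rec, l))
    }, numeric(1))
    expect_true(all(snrs >= 9 & snrs <= 37),
                info = sprintf("seed %d: range %.2f..%.2f", seed,
                               min(snrs), max(snrs)))
  }
})

test_that("beat template validation rejects malformed wave sets", {
  comp <- beat_template()$components
  bad <- comp; bad$width[2] <- 0
  expect_error(beat_template(bad), "widths")
  bad <- comp; bad$center <- rev(bad$center)
  expect_error(beat_template(bad), "increasing")
  bad <- comp; bad$amplitude[1] <- 2 * max(abs(comp$amplitude))
  expect_error(beat_template(bad), "R wave")
})

test_that("awgn injection hits the requested per-lead noise power", {
  # lead with mean power exactly 4 -> 10 dB target means variance 0.4
  rec <- ecg_record(matrix(c(2, -2), 1, 16384), fs = 1000)
  nz <- add_awgn(rec, 10, seed = 5)
  noise <- nz$signals[1, ] - rec$signals[1, ]
  expect_lt(abs(mean(noise^2) / 0.4 - 1), 0.05)
})

test_that("very large target SNR leaves the signal unchanged", {
  rec <- generate_ecg(duration_s = 2, seed = 1)
  nz <- add_awgn(rec, 300, seed = 2)
  expect_lt(max(abs(nz$signals - rec$signals)) / max(abs(rec$signals)),
            1e-10)
})

test_that("awgn refuses an all-zero lead", {
  rec <- ecg_record(rbind(sin(1:100), rep(0, 100)), fs = 100)
  expect_error(add_awgn(rec, 10, seed = 1), "all-zero lead")
})

test_that("noise streams are independent across leads", {
  rec <- generate_ecg(duration_s = 16.384, seed = 9)
  nz <- add_awgn(rec, 10, seed = 10)
  noise <- nz$signals - rec$signals
  cc <- cor(t(noise))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("sinusoidal interference lands on the requested frequency bin", {
  rec0 <- ecg_record(matrix(0, 1, 16384), fs = 1000)
  tone <- add_sinusoid(rec0, 50, 1e-3, seed = 3)
  spec <- Mod(fft(tone$signals[1, ]))[1:8193]
  peak_hz <- (which.max(spec) - 1) * 1000 / 16384
  expect_lt(abs(peak_hz - 50), 1000 / 16384)

  same <- add_sinusoid(rec0, 50, 0, seed = 3)
  expect_identical(same$signals, rec0$signals)

  expect_error(add_sinusoid(rec0, 600, 1e-3), "Nyquist")
})

test_that("a notch at the tone frequency undoes injected interference", {
  rec <- generate_ecg(duration_s = 20, seed = 21, n_leads = 1)
  tone <- add_sinusoid(rec, 50, 5e-4, seed = 22)
  seg <- extract_segment(tone, 1, start_s = 1, n_samples = 16384)
  k50 <- round(50 * 16384 / 1000) + 1
  before <- Mod(fft(seg$samples))[k50]
  after <- Mod(fft(notch_filter(seg)$samples))[k50]
  expect_gt(20 * log10(before / after), 20)
})
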