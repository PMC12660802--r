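seg_of <- function(x, fs = 1000) ecg_segment(x, fs)

test_that("high-pass removes DC and sub-cutoff drift, keeps the passband", {
  const <- seg_of(rep(1, 16384), 500)
  out <- highpass_filter(const)
  expect_lt(abs(mean(out$samples)), 1e-6)

  sos <- ecgdenoise:::design_iir(4, 0.5 / 250, "high", "butter")
  h <- Mod(ecgdenoise:::sos_freq_response(sos, c(0.05, 10), 500))
  expect_lt(20 * log10(h[1]), -20)           # 0.1 x cutoff: > 20 dB down
  expect_lt(abs(h[2] - 1), 0.01)             # 10 Hz within 1 %

  t5 <- (0:16383) / 500
  tone <- highpass_filter(seg_of(sin(2 * pi * 10 * t5), 500))
  expect_lt(abs(max(abs(tone$samples[3000:13000])) - 1), 0.01)
})

test_that("high-pass path resamples to the configured target rate", {
  rec <- generate_ecg(duration_s = 30, seed = 6, n_leads = 1)
  seg <- extract_segment(rec, 1)
  out <- highpass_filter(seg)
  expect_equal(out$fs, 500)
  expect_equal(length(out), 8192)
  # normalized and absolute-frequency designs are the same filter
  a <- highpass_filter(seg, highpass_config(normalized = TRUE))
  b <- highpass_filter(seg, highpass_config(normalized = FALSE))
  expect_identical(a$samples, b$samples)
})

test_that("Chebyshev II band-pass meets its design template", {
  sos <- ecgdenoise:::design_iir(6, c(0.5, 25) / 500, "pass", "cheby2",
                                 rs = 40)
  h_db <- 20 * log10(Mod(ecgdenoise:::sos_freq_response(
    sos, c(0.1, 0.5, 5, 10, 25, 50, 100), 1000)))
  expect_true(all(h_db[c(1, 2, 5, 6, 7)] <= -39.9))  # stopband >= 40 dB
  expect_true(all(abs(h_db[3:4]) < 1))               # passband within 1 dB

  t1 <- (0:16383) / 1000
  y50 <- cheby2_bandpass(seg_of(sin(2 * pi * 50 * t1)))
  att <- 20 * log10(max(abs(y50$samples[4000:16000])))
  expect_lt(att, -39)

  z <- cheby2_bandpass(seg_of(rep(0, 4096)))
  expect_equal(z$samples, rep(0, 4096))
  expect_error(cheby2_bandpass(seg_of(rnorm(1000), fs = 40)),
               "below Nyquist")
})

test_that("SOS designs agree with signal's transfer-function designs", {
  # moderate order where the (b, a) form is still well conditioned
  ba <- signal::butter(4, 0.2, "low")
  sos <- ecgdenoise:::design_iir(4, 0.2, "low", "butter")
  f <- seq(5, 495, by = 10)
  w <- exp(-1i * pi * f / 500)
  h_ba <- signal::polyval(rev(ba$b), w) / signal::polyval(rev(ba$a), w)
  h_sos <- ecgdenoise:::sos_freq_response(sos, f, 1000)
  expect_lt(max(abs(Mod(h_ba) - Mod(h_sos))), 1e-8)

  ba2 <- signal::cheby2(3, 30, 0.3, "high")
  sos2 <- ecgdenoise:::design_iir(3, 0.3, "high", "cheby2", rs = 30)
  h_ba2 <- signal::polyval(rev(ba2$b), w) / signal::polyval(rev(ba2$a), w)
  h_sos2 <- ecgdenoise:::sos_freq_response(sos2, f, 1000)
  expect_lt(max(abs(Mod(h_ba2) - Mod(h_sos2))), 1e-8)
})

test_that("notch filter is surgical around its centre frequency", {
  t1 <- (0:16383) / 1000
  tone50 <- seg_of(sin(2 * pi * 50 * t1))
  k50 <- round(50 * 16384 / 1000) + 1
  before <- Mod(fft(tone50$samples))[k50]
  after <- Mod(fft(notch_filter(tone50)$samples))[k50]
  expect_gt(20 * log10(before / after), 30)

  tone10 <- seg_of(sin(2 * pi * 10 * t1))
  y10 <- notch_filter(tone10)
  expect_lt(abs(max(abs(y10$samples[3000:13000])) - 1), 0.005)

  z <- notch_filter(seg_of(rep(0, 1024)))
  expect_equal(z$samples, rep(0, 1024))
})

test_that("notch bandwidth is f0 over Q", {
  expect_equal(notch_bandwidth(50, 26), 50 / 26)
  expect_equal(round(notch_bandwidth(50, 26), 2), 1.92)
  expect_equal(notch_bandwidth(50, 50), 1)
  expect_equal(notch_bandwidth(60, 30), 2)
  expect_error(notch_bandwidth(50, 0), "positive")
})

test_that("moving average behaves as a delay-compensated boxcar", {
  const <- seg_of(rep(2.5, 400))
  expect_equal(moving_average(const)$samples, rep(2.5, 400))

  imp <- seg_of(c(rep(0, 100), 1, rep(0, 99)))
  y <- moving_average(imp)$samples
  expect_equal(max(y), 1 / 20)
  expect_equal(sum(y > 0), 20)
  expect_equal(sum(y), 1)

  set.seed(41)
  wn <- seg_of(rnorm(16384))
  yv <- var(moving_average(wn)$samples[200:16000])
  expect_lt(abs(yv / (1 / 20) - 1), 0.15)

  expect_error(moving_average(seg_of(rnorm(10)), ma_config(15)),
               "window longer")
})

test_that("Savitzky-Golay reproduces polynomials and shrinks noise", {
  x <- (1:500) / 100
  cub <- seg_of(2 + x - 0.5 * x^2 + 0.3 * x^3)
  y <- savgol_smooth(cub)
  expect_lt(max(abs(y$samples[30:470] - cub$samples[30:470])), 1e-9)

  const <- seg_of(rep(1.7, 100))
  expect_equal(savgol_smooth(const)$samples, rep(1.7, 100),
               tolerance = 1e-12)

  set.seed(42)
  wn <- seg_of(rnorm(16384))
  gain <- sum(signal::sgolay(3, 35)[18, ]^2)
  yv <- var(savgol_smooth(wn)$samples[100:16000])
  expect_lt(abs(yv / gain - 1), 0.2)

  expect_error(sgs_config(window = 34), "odd")
  expect_error(sgs_config(window = 5, polyorder = 7), "smaller")
})

test_that("Kalman recursion honours its limiting regimes", {
  set.seed(43)
  z <- 5 + rnorm(400)
  # measurement noise -> 0: observations trusted fully
  out <- kalman_denoise(seg_of(z, 100),
                        kalman_config(measurement_noise_r = 1e-12))
  expect_lt(max(abs(out$samples - z) / abs(z)), 1e-6)
  # static state (q = 0, c = 1): estimate is the running mean
  kr <- kalman_recursion(z, kalman_config(process_noise_q = 0,
                                          measurement_noise_r = 1, p0 = 1))
  expect_equal(kr$estimate, cumsum(z) / seq_along(z), tolerance = 1e-12)
})

test_that("Kalman steady state matches the scalar Riccati root", {
  ss <- kalman_steady_state(kalman_config())
  q <- 1e-4; r <- 1e-2
  p_star <- (-q + sqrt(q^2 + 4 * q * r)) / 2      # root of P^2 + Pq - rq
  k_star <- (p_star + q) / (p_star + q + r)
  expect_equal(ss$gain, k_star, tolerance = 1e-6)
  expect_equal(round(ss$gain, 4), 0.0951)
  # posterior variance decreases monotonically to the fixed point
  kr <- kalman_recursion(rnorm(2000), kalman_config())
  expect_true(all(diff(kr$variance) <= 1e-12))
  expect_equal(kr$variance[2000], p_star, tolerance = 1e-9)
})

test_that("butter utilities implement the cutoff demonstrations", {
  t1 <- (0:16383) / 1000
  bs <- butter_utility(seg_of(sin(2 * pi * 50 * t1)), "bandstop",
                       c(48, 52))
  expect_lt(20 * log10(max(abs(bs$samples[3000:13000]))), -30)

  lp <- butter_utility(seg_of(sin(2 * pi * 5 * t1)), "lowpass", 35)
  expect_lt(abs(max(abs(lp$samples[3000:13000])) - 1), 0.01)

  z <- butter_utility(seg_of(rep(0, 2048)), "lowpass", 35)
  expect_equal(z$samples, rep(0, 2048))
  expect_error(butter_utility(seg_of(rnorm(100)), "lowpass", 600),
               "Nyquist")
})

test_that("linear filters are linear; Kalman is scale-equivariant", {
  set.seed(44)
  x <- rnorm(4096); y <- rnorm(4096)
  a <- 2.3; b <- -0.7
  linf <- list(
    function(s) cheby2_bandpass(s)$samples,
    function(s) notch_filter(s)$samples,
    function(s) moving_average(s)$samples,
    function(s) savgol_smooth(s)$samples,
    function(s) butter_utility(s, "lowpass", 35)$samples
  )
  for (f in linf) {
    lhs <- f(seg_of(a * x + b * y))
    rhs <- a * f(seg_of(x)) + b * f(seg_of(y))
    expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
  }
  k1 <- kalman_denoise(seg_of(x))$samples
  k3 <- kalman_denoise(seg_of(3 * x))$samples
  expect_lt(max(abs(k3 - 3 * k1)) / max(abs(k3)), 1e-9)
})

test_that("zero-phase paths introduce no group delay", {
  # band-limited bump: cross-correlation peak must sit at lag 0
  t1 <- (0:8191) / 500
  bump <- exp(-(t1 - 8)^2 / 0.5) * sin(2 * pi * 6 * t1)
  for (out in list(highpass_filter(seg_of(bump, 500))$samples,
                   butter_utility(seg_of(bump, 500), "lowpass",
                                  35)$samples)) {
    cc <- ccf(out, bump, lag.max = 20, plot = FALSE)
    expect_equal(cc$lag[which.max(cc$acf)], 0)
  }
  # the symmetric-kernel Savitzky-Golay path is delay-free too
  sg <- savgol_smooth(seg_of(bump, 500))$samples
  cc <- ccf(sg, bump, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("denoisers beat the noisy input on a 10 dB segment", {
  pair <- test_segment_pair(seed = 101)
  base <- snr_filtered(pair$clean, pair$noisy)
  for (f in list(savgol_smooth, kalman_denoise)) {
    expect_gt(snr_filtered(pair$clean, f(pair$noisy)), base)
  }
})
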