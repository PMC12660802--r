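# Independent brute-force (explicit-loop) implementations of the metric
# suite, used as oracles against the vectorised package code.

oracle_mse <- function(x, xh) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - xh[i])^2
  s / length(x)
}

oracle_rmse <- function(x, xh) sqrt(oracle_mse(x, xh))

oracle_snr_filtered <- function(x, xh) {
  es <- 0; ee <- 0
  for (i in seq_along(x)) {
    es <- es + x[i]^2
    ee <- ee + (x[i] - xh[i])^2
  }
  10 * log10(es / ee)
}

oracle_psnr <- function(x, xh) {
  pk <- 0
  for (i in seq_along(x)) if (abs(x[i]) > pk) pk <- abs(x[i])
  10 * log10(pk^2 / oracle_mse(x, xh))
}

oracle_prd <- function(x, xh) {
  es <- 0; ee <- 0
  for (i in seq_along(x)) {
    es <- es + x[i]^2
    ee <- ee + (x[i] - xh[i])^2
  }
  100 * sqrt(ee / es)
}

oracle_pearson <- function(x, xh) {
  n <- length(x)
  mx <- 0; my <- 0
  for (i in seq_len(n)) {
    mx <- mx + x[i] / n
    my <- my + xh[i] / n
  }
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (xh[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (xh[i] - my)^2
  }
  sxy / (sqrt(sxx) * sqrt(syy))
}

oracle_pop_sd <- function(x) {
  n <- length(x)
  m <- 0
  for (i in seq_len(n)) m <- m + x[i] / n
  s <- 0
  for (i in seq_len(n)) s <- s + (x[i] - m)^2
  sqrt(s / n)
}

oracle_snr_original <- function(x) {
  mx <- x[1]; mn <- x[1]
  for (i in seq_along(x)) {
    if (x[i] > mx) mx <- x[i]
    if (x[i] < mn) mn <- x[i]
  }
  20 * log10((mx - mn) / oracle_pop_sd(x))
}

# two-pass mean (sum, then a refinement pass) so the oracle's central
# moments are conditioned like any careful textbook implementation
oracle_mean <- function(x) {
  s <- 0
  for (i in seq_along(x)) s <- s + x[i]
  m0 <- s / length(x)
  d <- 0
  for (i in seq_along(x)) d <- d + (x[i] - m0)
  m0 + d / length(x)
}

oracle_moment <- function(x, k) {
  m <- oracle_mean(x)
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - m)^k
  s / length(x)
}

oracle_kurtosis <- function(x) {
  oracle_moment(x, 4) / oracle_moment(x, 2)^2 - 3
}

oracle_skewness <- function(x) {
  oracle_moment(x, 3) / oracle_moment(x, 2)^1.5
}

# linear-interpolation (type 7) quantile, written out longhand
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

oracle_iqr <- function(x) {
  oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25)
}

rel_err <- function(a, b) {
  abs(a - b) / max(abs(a), abs(b), .Machine$double.eps)
}
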