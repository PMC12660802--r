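#' Soft (or hard) shrinkage of a value against a threshold
#'
#' Soft thresholding shrinks magnitudes toward zero by `lam` and zeroes
#' anything smaller: `sign(v) * max(|v| - lam, 0)`.
#'
#' @param v Numeric vector of coefficients.
#' @param lam Non-negative threshold.
#' @return Thresholded vector.
#' @export
soft_threshold <- function(v, lam) {
  if (lam < 0) stop("threshold must be non-negative")
  sign(v) * pmax(abs(v) - lam, 0)
}

hard_threshold <- function(v, lam) {
  if (lam < 0) stop("threshold must be non-negative")
  v * (abs(v) > lam)
}

#' Robust noise-scale estimate from coefficients
#'
#' Median absolute deviation about the median, rescaled by 1/0.6745 so
#' that Gaussian input of standard deviation `s` yields approximately `s`.
#' The standard noise estimator applied to wavelet detail coefficients.
#'
#' @param coeffs Numeric vector.
#' @return Estimated scale (same units as `coeffs`).
#' @export
mad_sigma <- function(coeffs) {
  if (length(coeffs) < 1L) stop("empty coefficient vector")
  stats::median(abs(coeffs - stats::median(coeffs))) / 0.6745
}

#' @rdname filter_configs
#' @param wavelet Wavelet name, one of db4, db5, db6, sym4, sym5, coif3,
#'   coif4, coif5, bior3.5, rbio3.9.
#' @param level Decomposition depth (3-6 in the benchmark grid).
#' @param threshold_scale Multiplier on the per-level universal threshold
#'   `sigma_j * sqrt(2 log N)`; 0 disables shrinkage.
#' @param threshold_mode `"soft"` or `"hard"`.
#' @export
swt_config <- function(wavelet = "rbio3.9", level = 5,
                       threshold_scale = 0.5, threshold_mode = "soft") {
  if (!wavelet %in% names(.wavelet_banks)) {
    stop("unknown wavelet name: ", wavelet)
  }
  if (level < 1) stop("level must be >= 1")
  if (threshold_scale < 0) stop("threshold scale must be non-negative")
  threshold_mode <- match.arg(threshold_mode, c("soft", "hard"))
  new_filter_config("swt", "swt_config", wavelet = wavelet,
                    level = as.integer(level),
                    threshold_scale = threshold_scale,
                    threshold_mode = threshold_mode)
}

#' @export
apply_filter.swt_config <- function(config, segment) {
  swt_denoise(segment, config)
}

# Undecimated (stationary) wavelet transform, computed per level in the
# frequency domain with periodic boundary handling: at level j the analysis
# filters are upsampled by 2^(j-1) (algorithme a trous), which in the DFT
# domain is index decimation of the base filter response. Input length must
# be a multiple of 2^level (the caller pads).
swt_forward <- function(x, wavelet, level) {
  bank <- .wavelet_banks[[wavelet]]
  n <- length(x)
  idx0 <- 0:(n - 1)
  Hd <- stats::fft(c(bank$dec_lo, numeric(n - length(bank$dec_lo))))
  Gd <- stats::fft(c(bank$dec_hi, numeric(n - length(bank$dec_hi))))
  a_hat <- stats::fft(x)
  details <- vector("list", level)
  for (j in seq_len(level)) {
    s <- 2^(j - 1)
    up <- (idx0 * s) %% n + 1L
    d_hat <- a_hat * Gd[up]
    a_hat <- a_hat * Hd[up]
    details[[j]] <- Re(stats::fft(d_hat, inverse = TRUE)) / n
  }
  list(approx = Re(stats::fft(a_hat, inverse = TRUE)) / n,
       details = details, n = n, wavelet = wavelet, level = level)
}

# Inverse of swt_forward. Per level, the two synthesis branches are summed
# and divided by the combined transfer function H*Hrec + G*Grec, which for
# a perfect-reconstruction bank is a pure delay of magnitude 2 at every
# frequency, so the division is exact and stable.
swt_inverse <- function(dec) {
  bank <- .wavelet_banks[[dec$wavelet]]
  n <- dec$n
  idx0 <- 0:(n - 1)
  Hd <- stats::fft(c(bank$dec_lo, numeric(n - length(bank$dec_lo))))
  Gd <- stats::fft(c(bank$dec_hi, numeric(n - length(bank$dec_hi))))
  Hr <- stats::fft(c(bank$rec_lo, numeric(n - length(bank$rec_lo))))
  Gr <- stats::fft(c(bank$rec_hi, numeric(n - length(bank$rec_hi))))
  a_hat <- stats::fft(dec$approx)
  for (j in rev(seq_len(dec$level))) {
    s <- 2^(j - 1)
    up <- (idx0 * s) %% n + 1L
    d_hat <- stats::fft(dec$details[[j]])
    a_hat <- (a_hat * Hr[up] + d_hat * Gr[up]) /
      (Hd[up] * Hr[up] + Gd[up] * Gr[up])
  }
  Re(stats::fft(a_hat, inverse = TRUE)) / n
}

#' Stationary wavelet transform denoising
#'
#' Shift-invariant wavelet shrinkage: the segment is decomposed with the
#' undecimated wavelet transform to the configured level, each detail band
#' is thresholded at `lambda_j = threshold_scale * sigma_j * sqrt(2 log N)`
#' where `sigma_j` is the robust MAD noise estimate of that band
#' ([mad_sigma()]), the approximation band is left untouched, and the
#' signal is reconstructed. With `threshold_scale = 0` the round trip is
#' exact to floating-point precision.
#'
#' Segments whose length is not a multiple of `2^level` are symmetrically
#' padded before the transform and cropped afterwards; the protocol length
#' 16,384 needs no padding at level 5.
#'
#' @param segment An [ecg_segment()].
#' @param config An [swt_config()].
#' @return Denoised [ecg_segment()].
#' @export
swt_denoise <- function(segment, config = swt_config()) {
  stopifnot(inherits(segment, "ecg_segment"))
  x <- segment$samples
  n <- length(x)
  block <- 2^config$level
  pad <- (block - n %% block) %% block
  if (pad > 0) {
    if (pad > n) {
      reps <- c(x, rev(x))
      while (length(reps) < n + pad) reps <- c(reps, rev(reps))
      xp <- reps[seq_len(n + pad)]
    } else {
      xp <- c(x, rev(x)[seq_len(pad)])
    }
  } else {
    xp <- x
  }
  dec <- swt_forward(xp, config$wavelet, config$level)
  shrink <- switch(config$threshold_mode, soft = soft_threshold,
                   hard = hard_threshold)
  if (config$threshold_scale > 0) {
    nn <- length(xp)
    for (j in seq_len(config$level)) {
      lam <- config$threshold_scale * mad_sigma(dec$details[[j]]) *
        sqrt(2 * log(nn))
      dec$details[[j]] <- shrink(dec$details[[j]], lam)
    }
  }
  segment_like(segment, swt_inverse(dec)[seq_len(n)])
}
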