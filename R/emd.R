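#' @rdname filter_configs
#' @param max_imfs Maximum number of intrinsic mode functions to extract;
#'   `NULL` means `floor(log2(N)) - 1`.
#' @param max_sifts Sifting iteration cap per IMF.
#' @param sift_threshold Cauchy-style stopping threshold on the normalised
#'   change between consecutive sifts.
#' @export
emd_config <- function(lowcut_hz = 0.5, highcut_hz = 36, max_imfs = NULL,
                       max_sifts = 10, sift_threshold = 0.2) {
  if (lowcut_hz <= 0 || lowcut_hz >= highcut_hz) {
    stop("need 0 < lowcut < highcut")
  }
  new_filter_config("emd", "emd_config", lowcut_hz = lowcut_hz,
                    highcut_hz = highcut_hz, max_imfs = max_imfs,
                    max_sifts = max_sifts,
                    sift_threshold = sift_threshold)
}

#' @export
apply_filter.emd_config <- function(config, segment) {
  emd_filter(segment, config)
}

# Local extrema of x as index vectors; plateaus are collapsed by carrying
# the previous slope sign.
find_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  # carry slope sign across flats
  for (i in which(s == 0)) s[i] <- if (i > 1) s[i - 1] else 0
  ds <- diff(s)
  list(maxima = which(ds < 0) + 1L, minima = which(ds > 0) + 1L)
}

# Cubic-spline envelope through the given extrema, with the first/last two
# extrema mirrored beyond both ends to tame boundary swings.
envelope_spline <- function(idx, val, n) {
  m <- length(idx)
  left_i <- 2 - idx[min(2, m):1]
  left_v <- val[min(2, m):1]
  right_i <- 2 * n - idx[m:max(1, m - 1)]
  right_v <- val[m:max(1, m - 1)]
  xi <- c(left_i, idx, right_i)
  yi <- c(left_v, val, right_v)
  keep <- !duplicated(xi)
  stats::spline(xi[keep], yi[keep], xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by standard
#' sifting: cubic-spline envelopes through the local maxima and minima are
#' averaged and subtracted until the component's mean envelope is
#' negligible (Cauchy criterion below `sift_threshold`, at most
#' `max_sifts` iterations), then the IMF is removed and sifting restarts
#' on the remainder. Extraction stops when the remainder has fewer than
#' two maxima or two minima (it is then monotone-like) or `max_imfs` is
#' reached. By construction the IMFs plus the residual sum exactly to the
#' input.
#'
#' @param segment An [ecg_segment()] or numeric vector.
#' @param config An [emd_config()] (only the sifting controls are used).
#' @return A list of class `emd_decomposition`: `imfs` (list of numeric
#'   vectors, highest frequency first), `residual`, `n`.
#' @export
emd_decompose <- function(segment, config = emd_config()) {
  x <- as_samples(segment)
  n <- length(x)
  if (n < 4L) stop("signal too short for decomposition")
  max_imfs <- if (is.null(config$max_imfs)) {
    max(1L, floor(log2(n)) - 1L)
  } else {
    config$max_imfs
  }
  imfs <- list()
  r <- x
  repeat {
    ex <- find_extrema(r)
    if (length(ex$maxima) < 2L || length(ex$minima) < 2L ||
        length(imfs) >= max_imfs) {
      break
    }
    h <- r
    for (it in seq_len(config$max_sifts)) {
      ex_h <- find_extrema(h)
      if (length(ex_h$maxima) < 2L || length(ex_h$minima) < 2L) break
      upper <- envelope_spline(ex_h$maxima, h[ex_h$maxima], n)
      lower <- envelope_spline(ex_h$minima, h[ex_h$minima], n)
      m <- (upper + lower) / 2
      h_new <- h - m
      sd_it <- sum(m^2) / (sum(h^2) + .Machine$double.eps)
      h <- h_new
      if (sd_it < config$sift_threshold) break
    }
    imfs[[length(imfs) + 1L]] <- h
    r <- r - h
  }
  structure(list(imfs = imfs, residual = r, n = n),
            class = "emd_decomposition")
}

#' @export
print.emd_decomposition <- function(x, ...) {
  cat(sprintf("<emd_decomposition> %d IMF(s) + residual, n = %d\n",
              length(x$imfs), x$n))
  invisible(x)
}

#' EMD-based band-pass denoising
#'
#' Decomposes the segment into IMFs, band-passes each IMF between the
#' configured cutoffs (zero-phase Butterworth, fourth-order prototype) and
#' reconstructs as the sum of the filtered IMFs plus the untouched
#' residual, so slow baseline trends survive while out-of-band content of
#' every oscillatory mode is removed.
#'
#' @param segment An [ecg_segment()].
#' @param config An [emd_config()].
#' @return Filtered [ecg_segment()].
#' @export
emd_filter <- function(segment, config = emd_config()) {
  stopifnot(inherits(segment, "ecg_segment"))
  nyq <- segment$fs / 2
  if (config$highcut_hz >= nyq) stop("highcut must be below Nyquist")
  dec <- emd_decompose(segment, config)
  if (length(dec$imfs) == 0L) return(segment)
  sos <- design_iir(4, c(config$lowcut_hz, config$highcut_hz) / nyq,
                    "pass", "butter")
  out <- dec$residual
  for (imf in dec$imfs) out <- out + sos_filtfilt(sos, imf)
  segment_like(segment, out)
}
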