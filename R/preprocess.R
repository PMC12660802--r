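#' Extract the protocol analysis segment from a record
#'
#' Slices one lead to a fixed-length excerpt. The defaults implement the
#' benchmark protocol: 2^14 = 16,384 samples (16.384 s at 1 kHz) starting
#' at the 10-second mark, skipping the settling artifacts common at the
#' beginning of clinical recordings. Indexing is 0-based and half-open:
#' samples `[round(start_s * fs), round(start_s * fs) + n_samples)` are
#' returned.
#'
#' @param record An [ecg_record()].
#' @param lead Lead name or 1-based lead index.
#' @param start_s Segment start time in seconds.
#' @param n_samples Number of samples to extract.
#' @return An [ecg_segment()].
#' @export
extract_segment <- function(record, lead, start_s = 10, n_samples = 16384) {
  stopifnot(inherits(record, "ecg_record"))
  if (is.character(lead)) {
    li <- match(lead, record$lead_names)
    if (is.na(li)) stop("unknown lead name: ", lead)
  } else {
    li <- as.integer(lead)
    if (li < 1 || li > nrow(record$signals)) stop("lead index out of range")
  }
  i0 <- round(start_s * record$fs)   # 0-based first index
  if (i0 < 0) stop("start_s must be non-negative")
  n_avail <- ncol(record$signals)
  if (i0 + n_samples > n_avail) {
    stop(sprintf(
      "record shorter than protocol: need %d samples from index %d, have %d",
      n_samples, i0, n_avail))
  }
  ecg_segment(record$signals[li, (i0 + 1):(i0 + n_samples)],
              fs = record$fs, start_time_s = i0 / record$fs,
              source_record = record$id,
              lead_name = record$lead_names[li])
}

#' Resample a signal by the Fourier method
#'
#' Frequency-domain resampling: the spectrum is truncated (down-sampling,
#' which is inherently anti-aliased) or zero-padded (up-sampling) so the
#' output has exactly `round(n * fs_out / fs_in)` samples. Sub-Nyquist tone
#' energy is preserved; the Nyquist bin is split/folded in the usual way.
#'
#' @param x Numeric vector or [ecg_segment()].
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @return Same type as `x`, resampled; a segment keeps its metadata and
#'   carries `fs = fs_out`.
#' @export
resample_signal <- function(x, fs_in = NULL, fs_out) {
  fs_in <- segment_fs(x, fs_in)
  if (fs_in <= 0 || fs_out <= 0) stop("sampling rates must be positive")
  s <- as_samples(x)
  n <- length(s)
  n_out <- round(n * fs_out / fs_in)
  if (n_out < 1) stop("resampling would produce an empty signal")
  y <- fourier_resample(s, n_out)
  segment_like(x, y, fs = fs_out)
}

# Core length-changing Fourier resampler (real signals).
fourier_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  nmin <- min(n, n_out)
  Y <- complex(length.out = n_out)
  nyq <- nmin %/% 2L + 1L                 # 1-based index of the fold point
  Y[1:nyq] <- X[1:nyq]
  if (nyq < nmin) {
    ntail <- nmin - nyq                   # negative-frequency bins kept
    Y[(n_out - ntail + 1L):n_out] <- X[(n - ntail + 1L):n]
  }
  if (nmin %% 2L == 0L) {
    if (n_out < n) {
      # fold the energy of the removed mirrored Nyquist bin
      Y[nyq] <- Y[nyq] + X[n - nmin + nyq]
    } else {
      # split the Nyquist bin between the two mirrored positions
      Y[nyq] <- Y[nyq] / 2
      Y[n_out - nmin %/% 2L + 1L] <- Y[nyq]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}
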