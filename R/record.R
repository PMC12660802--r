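#' Multi-lead ECG record
#'
#' Container for a sampled multi-lead ECG. Amplitudes are stored in volts
#' throughout the package; readers for formats that store millivolts or
#' microvolts convert on input.
#'
#' @param signals Numeric matrix, one row per lead, one column per sample.
#'   A single numeric vector is accepted and treated as a one-lead record.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param lead_names Character vector of lead names, one per row of
#'   `signals`. Defaults to the conventional 12-lead order when `signals`
#'   has 12 rows, otherwise `L1`, `L2`, ...
#' @param provenance Free-form tag describing where the record came from,
#'   e.g. `"synthetic"` or `"wfdb"`.
#' @param id Record identifier used when segments are traced back to their
#'   source.
#'
#' @return An object of class `ecg_record`: a list with elements `signals`,
#'   `fs`, `lead_names`, `provenance` and `id`.
#' @export
#' @examples
#' rec <- ecg_record(rbind(sin(1:100 / 5), cos(1:100 / 5)), fs = 100)
#' rec
ecg_record <- function(signals, fs, lead_names = NULL,
                       provenance = "unspecified", id = "record-1") {
  if (is.vector(signals) && is.numeric(signals)) {
    signals <- matrix(signals, nrow = 1L)
  }
  if (!is.matrix(signals) || !is.numeric(signals)) {
    stop("`signals` must be a numeric matrix (leads x samples)")
  }
  if (ncol(signals) < 1L) stop("record must contain at least one sample")
  if (!all(is.finite(signals))) stop("record contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)")
  }
  if (is.null(lead_names)) {
    lead_names <- if (nrow(signals) == 12L) {
      standard_lead_names()
    } else {
      paste0("L", seq_len(nrow(signals)))
    }
  }
  if (length(lead_names) != nrow(signals)) {
    stop("`lead_names` must have one entry per lead")
  }
  rownames(signals) <- lead_names
  structure(
    list(signals = signals, fs = as.numeric(fs),
         lead_names = as.character(lead_names),
         provenance = provenance, id = id),
    class = "ecg_record"
  )
}

#' Conventional 12-lead naming
#'
#' @return Character vector `I, II, III, aVR, aVL, aVF, V1..V6`.
#' @export
standard_lead_names <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> %d lead(s) x %d samples @ %g Hz (%.3f s), %s\n",
              x$id, nrow(x$signals), ncol(x$signals), x$fs,
              ncol(x$signals) / x$fs, x$provenance))
  cat("  leads:", paste(x$lead_names, collapse = ", "), "\n")
  invisible(x)
}

#' Single-lead ECG segment
#'
#' Fixed-length excerpt of one lead; the unit every filter and metric in the
#' package consumes and produces.
#'
#' @param samples Numeric vector of at least two finite samples (volts).
#' @param fs Sampling rate in Hz.
#' @param start_time_s Time of the first sample relative to the source
#'   record, in seconds.
#' @param source_record Identifier of the record the segment came from.
#' @param lead_name Name of the source lead.
#'
#' @return An object of class `ecg_segment`.
#' @export
ecg_segment <- function(samples, fs, start_time_s = 0,
                        source_record = NA_character_,
                        lead_name = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("a segment needs at least two samples")
  if (!all(is.finite(samples))) stop("segment contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         start_time_s = start_time_s,
         source_record = source_record, lead_name = lead_name),
    class = "ecg_segment"
  )
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("<ecg_segment> %d samples @ %g Hz, lead %s of %s, start %.3f s\n",
              length(x$samples), x$fs, x$lead_name, x$source_record,
              x$start_time_s))
  invisible(x)
}

#' @export
length.ecg_segment <- function(x) length(x$samples)

# Accept either a segment or a bare numeric vector in numeric-in/numeric-out
# helpers.
as_samples <- function(x) {
  if (inherits(x, "ecg_segment")) x$samples else as.numeric(x)
}

# Rebuild a segment around new samples, optionally at a new sampling rate.
segment_like <- function(template, samples, fs = NULL) {
  if (inherits(template, "ecg_segment")) {
    ecg_segment(samples,
                fs = if (is.null(fs)) template$fs else fs,
                start_time_s = template$start_time_s,
                source_record = template$source_record,
                lead_name = template$lead_name)
  } else {
    samples
  }
}

segment_fs <- function(x, default = NULL) {
  if (inherits(x, "ecg_segment")) return(x$fs)
  if (is.null(default)) stop("sampling rate required for bare numeric input")
  default
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
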