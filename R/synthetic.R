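#' PQRST beat template
#'
#' Describes one cardiac cycle as a sum of Gaussian bumps, one per wave.
#' Centers are expressed as fractions of the beat interval, widths in
#' seconds, amplitudes in volts. The default template gives an R peak of
#' 0.8 mV with conventional relative P/Q/S/T amplitudes, which places the
#' generated leads on the amplitude scale of clinical 12-lead recordings
#' (standard deviations on the order of 1e-4 V).
#'
#' @param components Data frame with columns `wave` (P, Q, R, S, T),
#'   `center` (fraction of beat in `[0, 1)`, strictly increasing), `width`
#'   (seconds, positive) and `amplitude` (volts; the R wave must have the
#'   largest magnitude).
#' @param heart_rate_bpm Mean heart rate in beats per minute.
#' @param hr_jitter_frac Relative standard deviation of the beat-to-beat
#'   interval (dimensionless).
#'
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(components = NULL, heart_rate_bpm = 70,
                          hr_jitter_frac = 0.04) {
  if (is.null(components)) {
    components <- data.frame(
      wave = c("P", "Q", "R", "S", "T"),
      center = c(0.10, 0.225, 0.25, 0.275, 0.45),
      width = c(0.025, 0.010, 0.012, 0.010, 0.045),
      amplitude = c(1.2e-4, -1.0e-4, 8.0e-4, -2.0e-4, 2.5e-4)
    )
  }
  stopifnot(is.data.frame(components),
            all(c("wave", "center", "width", "amplitude") %in%
                  names(components)))
  if (any(components$width <= 0)) stop("wave widths must be positive")
  if (any(diff(components$center) <= 0)) {
    stop("wave centers must be strictly increasing within a beat")
  }
  if (any(components$center < 0 | components$center >= 1)) {
    stop("wave centers must lie in [0, 1)")
  }
  r_amp <- abs(components$amplitude[components$wave == "R"])
  if (length(r_amp) != 1L || any(abs(components$amplitude) > r_amp)) {
    stop("the R wave must carry the largest amplitude magnitude")
  }
  if (heart_rate_bpm <= 0) stop("heart rate must be positive")
  if (hr_jitter_frac < 0) stop("heart-rate jitter must be non-negative")
  structure(list(components = components,
                 heart_rate_bpm = heart_rate_bpm,
                 hr_jitter_frac = hr_jitter_frac),
            class = "beat_template")
}

# Unit-projection PQRST train sampled on t = (0:(n-1))/fs.
beat_train <- function(template, n, fs) {
  rr_nom <- 60 / template$heart_rate_bpm
  dur <- n / fs
  n_beats <- ceiling(dur / rr_nom) + 2L
  eps <- stats::rnorm(n_beats, 0, template$hr_jitter_frac)
  rr <- rr_nom * pmax(0.5, 1 + eps)
  onsets <- cumsum(c(0, rr[-n_beats]))
  x <- numeric(n)
  comp <- template$components
  for (k in seq_len(n_beats)) {
    for (j in seq_len(nrow(comp))) {
      mu <- onsets[k] + comp$center[j] * rr[k]
      w <- comp$width[j]
      i0 <- max(1L, floor((mu - 5 * w) * fs) + 1L)
      i1 <- min(n, ceiling((mu + 5 * w) * fs) + 1L)
      if (i0 > n || i1 < 1L) next
      idx <- i0:i1
      t <- (idx - 1) / fs
      x[idx] <- x[idx] + comp$amplitude[j] * exp(-(t - mu)^2 / (2 * w^2))
    }
  }
  x
}

# Slow aperiodic baseline drift: two incommensurate sub-0.025 Hz sinusoids
# with random phase, scaled to a requested RMS. Kept slow enough that over a
# 16 s analysis window it behaves as a trend (well under half a cycle, at
# most one interior extremum), the way electrode/respiratory drift presents
# in resting recordings.
baseline_drift <- function(n, fs, rms) {
  t <- (0:(n - 1)) / fs
  f1 <- stats::runif(1, 0.004, 0.012)
  f2 <- stats::runif(1, 0.012, 0.025)
  a <- stats::runif(2, 0.5, 1)
  w <- a[1] * sin(2 * pi * f1 * t + stats::runif(1, 0, 2 * pi)) +
    a[2] * sin(2 * pi * f2 * t + stats::runif(1, 0, 2 * pi))
  w <- w - mean(w)      # DC is modelled by the explicit electrode offset
  s <- stats::sd(w)
  if (s == 0) return(rep(0, n))
  w * (rms / s)
}

# RMS of the unit-projection beat train for the default template; used to
# express drift/offset scales relative to the cardiac signal.
TRAIN_RMS <- 1.5e-4

#' Generate a synthetic multi-lead ECG record
#'
#' Builds a reproducible multi-lead ECG with known ground truth. A common
#' PQRST Gaussian-bump train (the cardiac source) is projected onto the
#' limb electrodes LA/RA/LL and onto the precordial sites; leads
#' I/II/III/aVR/aVL/aVF are then derived through [derive_bipolar_leads()]
#' and [derive_augmented_leads()], so the lead-algebra identities hold to
#' machine precision. Each electrode/precordial site additionally carries a
#' DC offset and slow (< 0.05 Hz) baseline drift, emulating raw clinical
#' recordings in which the majority of segment energy sits below 0.5 Hz.
#'
#' @param template A [beat_template()].
#' @param duration_s Record duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param n_leads Number of leads to return (1..12, taken in the
#'   conventional order I, II, III, aVR, aVL, aVF, V1..V6).
#' @param seed Integer seed fixing all randomness; `NULL` leaves the RNG
#'   state alone.
#' @param id Record identifier.
#'
#' @return An [ecg_record()] with provenance `"synthetic"`.
#' @export
#' @examples
#' rec <- generate_ecg(duration_s = 5, seed = 1)
#' rec
generate_ecg <- function(template = beat_template(), duration_s = 30,
                         fs = 1000, n_leads = 12, seed = NULL,
                         id = "synthetic-1") {
  if (duration_s <= 0 || fs <= 0) stop("duration and fs must be positive")
  n <- round(duration_s * fs)
  if (n < 1) stop("duration_s * fs must be at least 1 sample")
  if (n_leads < 1 || n_leads > 12) stop("n_leads must be in 1..12")
  with_seed(seed, {
    s <- beat_train(template, n, fs)
    # electrode projections of the cardiac source (dimensionless)
    p_la <- 0.10 + stats::rnorm(1, 0, 0.05)
    p_ra <- -0.50 + stats::rnorm(1, 0, 0.05)
    p_ll <- 0.60 + stats::rnorm(1, 0, 0.05)
    electrode <- function(p) {
      p * s +
        baseline_drift(n, fs, stats::runif(1, 0.7, 1.4) * TRAIN_RMS) +
        sample(c(-1, 1), 1) * stats::runif(1, 1.0, 2.0) * TRAIN_RMS
    }
    la <- electrode(p_la); ra <- electrode(p_ra); ll <- electrode(p_ll)
    bip <- derive_bipolar_leads(la, ra, ll)
    aug <- derive_augmented_leads(bip$I, bip$II, bip$III)
    prec_proj <- c(-0.30, 0.50, 0.80, 1.10, 1.00, 0.85) +
      stats::rnorm(6, 0, 0.05)
    prec <- lapply(prec_proj, electrode)
    leads <- c(bip, aug, prec)
    sig <- do.call(rbind, leads)[seq_len(n_leads), , drop = FALSE]
    ecg_record(sig, fs = fs,
               lead_names = standard_lead_names()[seq_len(n_leads)],
               provenance = "synthetic", id = id)
  })
}

#' Add white Gaussian noise at an exact per-lead SNR
#'
#' Each lead `i` receives an independent Gaussian noise stream whose
#' variance is set from that lead's own average power,
#' `P_noise_i = P_signal_i / 10^(SNR/10)` with
#' `P_signal_i = mean(x_i^2)` (the mean of squared samples, DC included).
#' All leads therefore share the same target SNR while their noise
#' realisations are independent.
#'
#' @param record An [ecg_record()].
#' @param target_snr_db Target signal-to-noise ratio in dB.
#' @param seed Integer seed for the noise streams; `NULL` uses the current
#'   RNG state.
#' @return A new `ecg_record` with noise added.
#' @export
add_awgn <- function(record, target_snr_db, seed = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is.finite(target_snr_db)) stop("target_snr_db must be finite")
  p_sig <- rowMeans(record$signals^2)
  if (any(p_sig == 0)) {
    stop("all-zero lead: per-lead signal power undefined for SNR targeting")
  }
  with_seed(seed, {
    n <- ncol(record$signals)
    noise_sd <- sqrt(p_sig / 10^(target_snr_db / 10))
    noise <- t(vapply(noise_sd, function(s) stats::rnorm(n, 0, s),
                      numeric(n)))
    out <- record
    out$signals <- record$signals + noise
    rownames(out$signals) <- record$lead_names
    out
  })
}

#' Add a sinusoidal interference tone
#'
#' Models narrow-band contamination such as 50/60 Hz power-line
#' interference, or (at sub-hertz frequencies) sinusoidal baseline wander.
#' The phase is randomised per lead when not supplied.
#'
#' @param record An [ecg_record()].
#' @param freq Tone frequency in Hz; must be below the Nyquist frequency.
#' @param amplitude Tone amplitude in volts.
#' @param phase Phase in radians: a scalar or one value per lead. `NULL`
#'   draws an independent uniform phase per lead.
#' @param seed Integer seed for the random phases.
#' @return A new `ecg_record` with the tone added to every lead.
#' @export
add_sinusoid <- function(record, freq, amplitude, phase = NULL, seed = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  if (freq >= record$fs / 2) {
    stop("tone frequency must be below the Nyquist frequency fs/2")
  }
  if (freq < 0 || amplitude < 0) stop("freq and amplitude must be >= 0")
  n_leads <- nrow(record$signals)
  with_seed(seed, {
    ph <- if (is.null(phase)) {
      stats::runif(n_leads, 0, 2 * pi)
    } else {
      rep_len(phase, n_leads)
    }
    t <- (0:(ncol(record$signals) - 1)) / record$fs
    out <- record
    for (i in seq_len(n_leads)) {
      out$signals[i, ] <- record$signals[i, ] +
        amplitude * sin(2 * pi * freq * t + ph[i])
    }
    out
  })
}
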