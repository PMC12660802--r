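#' Mean squared error and its root
#'
#' `MSE = sum((x - xhat)^2) / N`, `RMSE = sqrt(MSE)`; the average squared
#' deviation of the filtered signal from the original.
#'
#' @param x Original signal (numeric vector or [ecg_segment()]).
#' @param xhat Filtered signal of the same length.
#' @return Named numeric vector `c(mse = , rmse = )` in volts^2 / volts.
#' @export
mse_rmse <- function(x, xhat) {
  x <- as_samples(x); xhat <- as_samples(xhat)
  check_pair(x, xhat)
  mse <- mean((x - xhat)^2)
  c(mse = mse, rmse = sqrt(mse))
}

#' Residual signal-to-noise ratio of a filtered signal
#'
#' `SNR_filtered = 10 * log10(E_signal / E_error)` with
#' `E_signal = sum(x^2)` and `E_error = sum((x - xhat)^2)`: the filtering
#' residual `x - xhat` stands in for the (unobservable) noise. Returns
#' `Inf` when `xhat` equals `x` exactly.
#'
#' @inheritParams mse_rmse
#' @return SNR in dB.
#' @export
snr_filtered <- function(x, xhat) {
  x <- as_samples(x); xhat <- as_samples(xhat)
  check_pair(x, xhat)
  e_sig <- sum(x^2)
  if (e_sig == 0) stop("zero signal energy: SNR undefined")
  e_err <- sum((x - xhat)^2)
  if (e_err == 0) return(Inf)
  10 * log10(e_sig / e_err)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 * log10(MAX(x)^2 / MSE)`. For bipolar signals the signal
#' peak `MAX(x)` is taken as `max(abs(x))` by default; set
#' `peak = "max"` to use the signed maximum instead. Returns `Inf` when
#' the two signals are identical.
#'
#' @inheritParams mse_rmse
#' @param peak Either `"absmax"` (default) or `"max"`.
#' @return PSNR in dB.
#' @export
psnr <- function(x, xhat, peak = c("absmax", "max")) {
  peak <- match.arg(peak)
  x <- as_samples(x); xhat <- as_samples(xhat)
  check_pair(x, xhat)
  pk <- if (peak == "absmax") max(abs(x)) else max(x)
  mse <- mean((x - xhat)^2)
  if (mse == 0) return(Inf)
  10 * log10(pk^2 / mse)
}

#' Percentage root-mean-square difference
#'
#' `PRD = 100 * sqrt(sum((x - xhat)^2) / sum(x^2))`. The denominator is
#' the raw (not mean-subtracted) signal energy, so a filter that removes a
#' DC offset is charged for it. Algebraically tied to [snr_filtered()] via
#' `SNR = 40 - 20*log10(PRD)`.
#'
#' @inheritParams mse_rmse
#' @return PRD in percent (>= 0).
#' @export
prd <- function(x, xhat) {
  x <- as_samples(x); xhat <- as_samples(xhat)
  check_pair(x, xhat)
  e_sig <- sum(x^2)
  if (e_sig == 0) stop("zero signal energy: PRD undefined")
  100 * sqrt(sum((x - xhat)^2) / e_sig)
}

#' Pearson correlation between original and filtered signal
#'
#' Standard centred product-moment correlation; 1 means the filtered
#' signal is an increasing affine image of the original.
#'
#' @inheritParams mse_rmse
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, xhat) {
  x <- as_samples(x); xhat <- as_samples(xhat)
  check_pair(x, xhat)
  if (stats::var(x) == 0 || stats::var(xhat) == 0) {
    stop("zero-variance input: correlation undefined")
  }
  stats::cor(x, xhat)
}

#' Heuristic SNR of a single signal
#'
#' `SNR_original = 20 * log10(Range(x) / sd(x))` with the peak-to-peak
#' range as the amplitude estimate and the population standard deviation
#' (ddof 0) as the noise estimate. The factor 20 applies because the ratio
#' compares amplitudes, not powers. A quick quality estimate when no clean
#' reference exists.
#'
#' @param x Numeric vector or [ecg_segment()].
#' @return Heuristic SNR in dB.
#' @export
snr_original_heuristic <- function(x) {
  x <- as_samples(x)
  s <- pop_sd(x)
  if (s == 0) stop("constant signal: heuristic SNR undefined")
  20 * log10((max(x) - min(x)) / s)
}

#' Distribution descriptors of a signal
#'
#' Fisher excess kurtosis and skewness (both population moments, no bias
#' correction; a Gaussian gives kurtosis 0), interquartile range with
#' linear-interpolation (type 7) quantiles, and population standard
#' deviation. Constant input yields `NaN` kurtosis/skewness.
#'
#' @param x Numeric vector or [ecg_segment()].
#' @return Named numeric vector
#'   `c(kurtosis_excess =, skewness =, iqr =, std_dev =)`.
#' @export
distribution_stats <- function(x) {
  x <- as_samples(x)
  if (length(x) < 2L) stop("need at least two samples")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  kur <- if (m2 == 0) NaN else mean((x - m)^4) / m2^2 - 3
  ske <- if (m2 == 0) NaN else mean((x - m)^3) / m2^1.5
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  c(kurtosis_excess = kur, skewness = ske,
    iqr = q[2] - q[1], std_dev = sqrt(m2))
}

#' Full eleven-statistic quality report
#'
#' Bundles the complete metric suite for one (original, filtered) pair:
#' error metrics and correlation compare `xhat` against `x`; the
#' distribution descriptors are computed on the filtered signal `xhat`;
#' the heuristic SNR is computed on the original `x`.
#'
#' @inheritParams mse_rmse
#' @return An object of class `metric_report`: a named list with elements
#'   `mse`, `rmse`, `psnr_db`, `prd_pct`, `pearson_r`, `snr_filtered_db`,
#'   `snr_original_db`, `kurtosis_excess`, `skewness`, `iqr`, `std_dev`.
#' @export
#' @examples
#' x <- sin(1:1000 / 20)
#' compute_all(x, x + rnorm(1000, 0, 0.05))
compute_all <- function(x, xhat) {
  xs <- as_samples(x); xh <- as_samples(xhat)
  check_pair(xs, xh)
  er <- mse_rmse(xs, xh)
  ds <- distribution_stats(xh)
  rep <- list(
    mse = unname(er["mse"]),
    rmse = unname(er["rmse"]),
    psnr_db = psnr(xs, xh),
    prd_pct = prd(xs, xh),
    pearson_r = if (stats::var(xs) > 0 && stats::var(xh) > 0) {
      pearson_r(xs, xh)
    } else {
      NaN
    },
    snr_filtered_db = snr_filtered(xs, xh),
    snr_original_db = snr_original_heuristic(xs),
    kurtosis_excess = unname(ds["kurtosis_excess"]),
    skewness = unname(ds["skewness"]),
    iqr = unname(ds["iqr"]),
    std_dev = unname(ds["std_dev"])
  )
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

check_pair <- function(x, xhat) {
  if (length(x) != length(xhat)) {
    stop("signals must have equal lengths (", length(x), " vs ",
         length(xhat), ")")
  }
  if (length(x) < 1L) stop("empty signal")
  if (!all(is.finite(x)) || !all(is.finite(xhat))) {
    stop("signals must be finite")
  }
  invisible(TRUE)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
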