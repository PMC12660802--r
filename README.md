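# ecgdenoise

Benchmarking denoising methods for multi-lead ECG signals in R.

Raw electrocardiograms are contaminated by baseline wander, power-line
interference and broadband noise; choosing a filter is a trade-off between
noise suppression and preservation of the PQRST morphology that carries the
diagnosis. `ecgdenoise` makes that trade-off measurable. It implements nine
parameterised denoisers —

* zero-phase Butterworth **high-pass** (0.5 Hz, order 4, at 500 Hz),
* **Chebyshev type II** band-pass (0.5–25 Hz, order 6, 40 dB stopband),
* biquad **notch** (50 Hz, Q = 26),
* **moving average** (20 samples, delay-compensated),
* **Savitzky–Golay** smoothing (window 35, order 3, mirror edges),
* scalar **Kalman** filtering (c = 1, q = 1e-4, r = 1e-2),
* **stationary wavelet transform** shrinkage (rbio3.9, level 5, soft
  universal threshold scaled by 0.5),
* **empirical mode decomposition** with per-IMF band-pass (0.5–36 Hz)
  reconstruction,
* **empirical wavelet transform** band selection (4 modes, locmaxmin
  boundaries, soft threshold),

— and scores each against an eleven-statistic quality suite: MSE, RMSE,
PSNR, PRD, Pearson correlation, residual SNR, heuristic SNR, excess
kurtosis, skewness, IQR and standard deviation. For a clean segment `x` and
filtered segment `x̂`,

    SNR_filtered = 10·log10( Σx² / Σ(x−x̂)² )      PRD(%) = 100·√( Σ(x−x̂)² / Σx² )

with the exact identity `SNR = 40 − 20·log10(PRD)`. Inputs are synthetic
12-lead records with known ground truth (Gaussian-bump PQRST trains plus DC
offset and sub-0.025 Hz baseline drift, AWGN injected at an exact per-lead
SNR), so no data download is needed; WFDB (format 16) and CSV readers let
the same pipeline run on real records such as the PTB diagnostic ECGs.

## Worked example

```r
library(ecgdenoise)

rec   <- generate_ecg(duration_s = 30, seed = 42)       # 12-lead, 1 kHz
noisy <- add_awgn(rec, target_snr_db = 10, seed = 7)    # exact per-lead SNR

clean_seg <- extract_segment(rec,   "II")               # 16,384 samples @ 10 s
noisy_seg <- extract_segment(noisy, "II")

den <- swt_denoise(noisy_seg, swt_config())             # the study optimum
compute_all(clean_seg, den)
#> <metric_report>
#>   mse              2.08345e-09
#>   rmse             4.56448e-05
#>   psnr_db          29.7578
#>   prd_pct          12.6834
#>   pearson_r        0.969594
#>   snr_filtered_db  17.9353
#>   snr_original_db  17.6537
#>   kurtosis_excess  3.75699
#>   skewness         1.60342
#>   iqr              0.000216335
#>   std_dev          0.000182308
```

The noisy segment itself scores PRD ≈ 60 % against the clean original;
wavelet shrinkage brings it to ≈ 12.7 % with correlation 0.970 — noise is
removed while the QRS morphology survives. The full comparison runs all
nine filters over many records and noise conditions:

```r
records <- lapply(1:20, function(i)
  generate_ecg(duration_s = 30, seed = 1000 + i, id = sprintf("syn-%02d", i)))
bench <- benchmark_run(records, noise_conditions = c(NA, 10, 15), seed = 1)
bench$comparison            # mean RMSE, median PSNR/PRD, mean correlation
bench$summaries$swt         # min/max/mean/median of every metric
```

At 10 dB AWGN the pooled medians rank SWT best (PRD ≈ 7 %, correlation
≈ 0.99) and the DC-removing high-pass / Chebyshev II filters worst (PRD
near 100 %, because ~80 % of raw segment energy lies below their 0.5 Hz
edge). `run_grid_search()` reproduces the per-filter parameter searches
(10 high-pass, 40 EWT and 320 SWT configurations via `default_grids()`),
and `time_filters()` reports relative runtimes (EMD slowest by orders of
magnitude, notch/SGS fastest).

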