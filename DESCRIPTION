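Package: ecgdenoise
Title: Comparative Denoising of Multi-Lead ECG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking electrocardiogram (ECG) denoising methods
    on multi-lead recordings. Implements nine parameterised denoisers
    (zero-phase Butterworth high-pass, Chebyshev type II band-pass, biquad
    notch, moving average, Savitzky-Golay smoothing, scalar Kalman filtering,
    stationary wavelet transform shrinkage, empirical mode decomposition with
    per-IMF band-pass reconstruction, and empirical wavelet transform band
    selection), an eleven-statistic signal-quality suite (MSE, RMSE, PSNR,
    PRD, Pearson correlation, residual and heuristic SNR, and distribution
    descriptors), SNR-targeted additive white Gaussian noise injection, a
    synthetic 12-lead ECG generator with known ground truth, parameter grid
    search, and benchmark aggregation. Readers and writers for CSV and WFDB
    records are included so the benchmark can also be run on real recordings
    such as the PTB Diagnostic ECG Database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
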