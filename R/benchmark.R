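#' The nine benchmark denoisers at their study-optimal settings
#'
#' @return Named list of `filter_config` objects: highpass, cheby2,
#'   kalman, ma, notch, sgs, emd, ewt, swt.
#' @export
default_filter_set <- function() {
  list(highpass = highpass_config(), cheby2 = cheby2_config(),
       kalman = kalman_config(), ma = ma_config(),
       notch = notch_config(), sgs = sgs_config(),
       emd = emd_config(), ewt = ewt_config(), swt = swt_config())
}

filter_constructors <- function() {
  list(highpass = highpass_config, cheby2 = cheby2_config,
       notch = notch_config, ma = ma_config, sgs = sgs_config,
       kalman = kalman_config, swt = swt_config, emd = emd_config,
       ewt = ewt_config, identity = identity_config)
}

#' Parameter grid specification
#'
#' @param filter_name Name of the filter the grid belongs to (must match a
#'   configuration constructor: highpass, cheby2, notch, ma, sgs, kalman,
#'   swt, emd, ewt).
#' @param ... Named axes: each argument is an ordered vector (or list) of
#'   candidate values for one constructor parameter.
#' @return Object of class `grid_spec`.
#' @export
#' @examples
#' grid_spec("highpass", order = 2:6, normalized = c(TRUE, FALSE))
grid_spec <- function(filter_name, ...) {
  axes <- list(...)
  if (length(axes) == 0) stop("a grid needs at least one axis")
  if (is.null(names(axes)) || any(names(axes) == "")) {
    stop("all axes must be named")
  }
  if (any(vapply(axes, length, integer(1)) == 0)) {
    stop("empty axis in grid")
  }
  if (!filter_name %in% names(filter_constructors())) {
    stop("unknown filter name: ", filter_name)
  }
  structure(list(filter_name = filter_name, axes = axes),
            class = "grid_spec")
}

#' Enumerate all valid configurations of a grid
#'
#' Expands the Cartesian product of the axes in deterministic
#' lexicographic order (first axis varies slowest) and instantiates a
#' configuration for every combination, dropping combinations the
#' configuration constructor rejects (e.g. a Savitzky-Golay polynomial
#' order not smaller than its window).
#'
#' @param spec A [grid_spec()].
#' @return List of `filter_config` objects; each carries the generating
#'   parameter combination as attribute `"params"`.
#' @export
enumerate_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  grid <- expand.grid(rev(spec$axes), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(spec$axes)), drop = FALSE]
  ctor <- filter_constructors()[[spec$filter_name]]
  out <- list()
  for (i in seq_len(nrow(grid))) {
    params <- lapply(grid[i, , drop = FALSE], function(col) {
      v <- if (is.list(col)) col[[1]] else col[1]
      v
    })
    names(params) <- names(spec$axes)
    cfg <- tryCatch(do.call(ctor, params), error = function(e) NULL)
    if (!is.null(cfg)) {
      attr(cfg, "params") <- params
      out[[length(out) + 1L]] <- cfg
    }
  }
  out
}

#' Benchmark parameter grids
#'
#' The per-filter search spaces explored by the study: 10 high-pass
#' combinations (orders 2-6, normalised design on/off), 40 EWT
#' configurations (soft/hard thresholding, ten threshold values, two
#' boundary methods) and 320 SWT configurations (ten wavelets, levels 3-6,
#' threshold scales 0.3-1.0), plus Chebyshev II and Kalman spaces.
#'
#' @return Named list of [grid_spec()] objects.
#' @export
default_grids <- function() {
  list(
    highpass = grid_spec("highpass", order = 2:6,
                         normalized = c(TRUE, FALSE)),
    cheby2 = grid_spec("cheby2", highcut_hz = c(25, 30, 35, 40),
                       order = c(4, 6, 8),
                       stopband_atten_db = c(40, 50, 60)),
    kalman = grid_spec("kalman", process_noise_q = 10^seq(-6, 2),
                       measurement_noise_r = 10^seq(-4, 1)),
    ewt = grid_spec("ewt", threshold_mode = c("soft", "hard"),
                    threshold = c(0, 1.5, 2, 2.5, 5, 7.5, 10, 12.5, 15, 25),
                    boundary_method = c("locmax", "locmaxmin")),
    swt = grid_spec("swt", wavelet = names(.wavelet_banks),
                    level = 3:6, threshold_scale = seq(0.3, 1, by = 0.1))
  )
}

# Score one config on one (clean, noisy) pair; reference is resampled when
# the filter changes the sampling rate (high-pass path).
score_pair <- function(config, clean, noisy) {
  filt <- apply_filter(config, noisy)
  ref <- if (!isTRUE(all.equal(clean$fs, filt$fs))) {
    resample_signal(clean, fs_out = filt$fs)
  } else {
    clean
  }
  list(snr = snr_filtered(ref, filt), prd = prd(ref, filt))
}

#' Grid search over a parameter space
#'
#' Evaluates every configuration of the grid on every supplied segment
#' pair and ranks configurations by the criterion (default: median
#' residual SNR, descending, with median PRD then enumeration order as
#' tie-breaks). Configurations that fail on any segment are excluded and
#' reported in the result table.
#'
#' @param segments List of pairs: each element is a list with elements
#'   `clean` (reference [ecg_segment()]) and optionally `noisy` (input to
#'   the filter; defaults to `clean`).
#' @param spec A [grid_spec()].
#' @param criterion `"median_snr"` (only criterion currently defined; kept
#'   as an argument so alternatives can be added).
#' @return List with `best_config` and `results`, a data frame of
#'   per-configuration scores in enumeration order.
#' @export
run_grid_search <- function(segments, spec, criterion = "median_snr") {
  criterion <- match.arg(criterion, "median_snr")
  if (length(segments) == 0) stop("need at least one segment")
  if (!is.null(segments$clean)) segments <- list(segments)
  configs <- enumerate_grid(spec)
  if (length(configs) == 0) stop("grid contains no valid configuration")
  res <- data.frame(config = seq_along(configs),
                    median_snr = NA_real_, median_prd = NA_real_,
                    failed = FALSE)
  for (i in seq_along(configs)) {
    scores <- tryCatch(
      lapply(segments, function(sp) {
        noisy <- if (is.null(sp$noisy)) sp$clean else sp$noisy
        score_pair(configs[[i]], sp$clean, noisy)
      }),
      error = function(e) NULL)
    if (is.null(scores)) {
      res$failed[i] <- TRUE
      next
    }
    res$median_snr[i] <- stats::median(vapply(scores, `[[`, numeric(1),
                                              "snr"))
    res$median_prd[i] <- stats::median(vapply(scores, `[[`, numeric(1),
                                              "prd"))
  }
  ok <- which(!res$failed)
  if (length(ok) == 0) stop("every configuration failed")
  ord <- ok[order(-res$median_snr[ok], res$median_prd[ok], ok)]
  params <- attr(configs[[ord[1]]], "params")
  res$params <- vapply(configs, function(cfg) {
    p <- attr(cfg, "params")
    paste(names(p), vapply(p, function(v) paste(format(v), collapse = "|"),
                           character(1)),
          sep = "=", collapse = ", ")
  }, character(1))
  list(best_config = configs[[ord[1]]], best_params = params,
       results = res)
}

condition_label <- function(cond) {
  if (is.na(cond)) "clean" else sprintf("%gdB", cond)
}

#' Evaluate one denoiser over records and noise conditions
#'
#' Implements the benchmark protocol for a single filter: for every record
#' and lead the clean protocol segment is extracted; for every noise
#' condition white Gaussian noise at the condition's target SNR is
#' injected into the record (per-lead independent noise, deterministic
#' seed derived per record x condition from the master seed), the noisy
#' segment is filtered, and the full metric suite is computed against the
#' CLEAN original segment (resampled when the filter changes the sampling
#' rate).
#'
#' @param records An [ecg_record()] or list of records.
#' @param filter_config A `filter_config`.
#' @param noise_conditions Numeric vector of target SNRs in dB; `NA` means
#'   the clean condition (no injected noise).
#' @param seed Master seed for the noise streams.
#' @param start_s,n_samples Protocol segment position and length.
#' @return Data frame: one row per record x lead x condition with the
#'   eleven metrics plus identifying columns.
#' @export
evaluate_dataset <- function(records, filter_config,
                             noise_conditions = c(NA, 10, 15), seed = 1,
                             start_s = 10, n_samples = 16384) {
  if (inherits(records, "ecg_record")) records <- list(records)
  if (length(records) == 0) stop("need at least one record")
  rows <- list()
  for (r in seq_along(records)) {
    rec <- records[[r]]
    for (ci in seq_along(noise_conditions)) {
      cond <- noise_conditions[ci]
      noisy_rec <- if (is.na(cond)) {
        rec
      } else {
        add_awgn(rec, cond,
                 seed = (seed + 1000003 * (r - 1) + 7919 * (ci - 1)) %%
                   2147483647)
      }
      for (lead in rec$lead_names) {
        row <- tryCatch({
          clean <- extract_segment(rec, lead, start_s, n_samples)
          noisy <- extract_segment(noisy_rec, lead, start_s, n_samples)
          filt <- apply_filter(filter_config, noisy)
          ref <- if (!isTRUE(all.equal(clean$fs, filt$fs))) {
            resample_signal(clean, fs_out = filt$fs)
          } else {
            clean
          }
          rep <- compute_all(ref, filt)
          cbind(data.frame(record = rec$id, lead = lead,
                           condition = condition_label(cond),
                           filter = filter_config$filter_name),
                as.data.frame(rep))
        }, error = function(e) {
          warning(sprintf("skipping %s/%s/%s: %s", rec$id, lead,
                          condition_label(cond), conditionMessage(e)))
          NULL
        })
        if (!is.null(row)) rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (length(rows) == 0) stop("no segment could be evaluated")
  do.call(rbind, rows)
}

#' Aggregate metric reports into a summary table
#'
#' Per metric and noise condition: minimum, maximum, arithmetic mean and
#' median over all lead-segments, excluding non-finite sentinel values
#' (whose count is reported).
#'
#' @param reports Data frame from [evaluate_dataset()] (possibly several
#'   filters' results bound together; aggregation is per filter if a
#'   `filter` column with several values is present).
#' @return Data frame of class `summary_table` with columns `filter`,
#'   `metric`, `condition`, `min`, `max`, `mean`, `median`, `n`,
#'   `n_excluded`.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1)
  id_cols <- c("record", "lead", "condition", "filter")
  metric_cols <- setdiff(names(reports), id_cols)
  filt_vals <- if ("filter" %in% names(reports)) {
    unique(reports$filter)
  } else {
    NA_character_
  }
  cond_vals <- if ("condition" %in% names(reports)) {
    unique(reports$condition)
  } else {
    NA_character_
  }
  out <- list()
  for (f in filt_vals) {
    for (cond in cond_vals) {
      sub <- reports
      if (!is.na(f)) sub <- sub[sub$filter == f, , drop = FALSE]
      if (!is.na(cond)) sub <- sub[sub$condition == cond, , drop = FALSE]
      if (nrow(sub) == 0) next
      for (m in metric_cols) {
        v <- sub[[m]]
        fin <- v[is.finite(v)]
        out[[length(out) + 1L]] <- data.frame(
          filter = f, metric = m, condition = cond,
          min = if (length(fin)) min(fin) else NA_real_,
          max = if (length(fin)) max(fin) else NA_real_,
          mean = if (length(fin)) mean(fin) else NA_real_,
          median = if (length(fin)) stats::median(fin) else NA_real_,
          n = length(fin), n_excluded = length(v) - length(fin))
      }
    }
  }
  structure(do.call(rbind, out), class = c("summary_table", "data.frame"))
}

#' Filter comparison table
#'
#' The cross-filter comparison in the shape of the study's final table:
#' per filter and condition, the mean RMSE, median PSNR, median PRD and
#' mean correlation (non-finite sentinels excluded).
#'
#' @param reports Combined data frame of [evaluate_dataset()] results for
#'   several filters.
#' @return Data frame with columns `filter`, `condition`, `mean_rmse`,
#'   `median_psnr`, `median_prd`, `mean_correlation`.
#' @export
comparison_table <- function(reports) {
  stopifnot(is.data.frame(reports), all(c("filter", "condition") %in%
                                          names(reports)))
  combos <- unique(reports[, c("filter", "condition")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- reports[reports$filter == combos$filter[i] &
                     reports$condition == combos$condition[i], ]
    fin <- function(v) v[is.finite(v)]
    data.frame(filter = combos$filter[i], condition = combos$condition[i],
               mean_rmse = mean(fin(sub$rmse)),
               median_psnr = stats::median(fin(sub$psnr_db)),
               median_prd = stats::median(fin(sub$prd_pct)),
               mean_correlation = mean(fin(sub$pearson_r)))
  })
  do.call(rbind, rows)
}

#' Run the full benchmark
#'
#' Evaluates every filter of `filters` on every record under every noise
#' condition, and returns the raw per-segment reports, per-filter summary
#' tables, the cross-filter comparison and a reproducibility manifest.
#' When `out_dir` is given, one CSV per filter, the comparison CSV and a
#' JSON manifest are written there.
#'
#' @param records List of [ecg_record()]s.
#' @param filters Named list of `filter_config`s
#'   (default [default_filter_set()]).
#' @param noise_conditions Numeric vector of target SNRs (dB), `NA` =
#'   clean.
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @return List with elements `reports`, `summaries`, `comparison`,
#'   `manifest`.
#' @export
benchmark_run <- function(records, filters = default_filter_set(),
                          noise_conditions = c(NA, 10, 15), seed = 1,
                          out_dir = NULL) {
  all_reports <- list()
  for (nm in names(filters)) {
    all_reports[[nm]] <- evaluate_dataset(records, filters[[nm]],
                                          noise_conditions, seed)
  }
  reports <- do.call(rbind, all_reports)
  rownames(reports) <- NULL
  summaries <- lapply(all_reports, aggregate_reports)
  comparison <- comparison_table(reports)
  manifest <- list(
    seed = seed,
    noise_conditions = ifelse(is.na(noise_conditions), "clean",
                              as.character(noise_conditions)),
    n_records = length(records),
    filters = lapply(filters, function(cfg)
      cfg[setdiff(names(cfg), "filter_name")]),
    package_version = as.character(utils::packageVersion("ecgdenoise")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(summaries)) {
      utils::write.csv(summaries[[nm]],
                       file.path(out_dir, paste0("summary_", nm, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(reports, file.path(out_dir, "reports.csv"),
                     row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
  }
  list(reports = reports, summaries = summaries, comparison = comparison,
       manifest = manifest)
}

#' Wall-clock comparison of denoisers
#'
#' Times repeated applications of each configuration to the same segment
#' and reports per-filter mean/median/min/max seconds plus the ratio of
#' each filter's median to the baseline filter's median. Absolute times
#' are hardware-dependent; only the relative ordering is meaningful.
#'
#' @param segment An [ecg_segment()].
#' @param configs Named list of `filter_config`s.
#' @param repetitions Number of timed runs per filter (>= 3).
#' @param baseline Name of the baseline filter for the ratio column.
#' @return Data frame with columns `filter`, `mean_s`, `median_s`,
#'   `min_s`, `max_s`, `ratio_to_baseline`.
#' @export
time_filters <- function(segment, configs = default_filter_set(),
                         repetitions = 5, baseline = "swt") {
  if (repetitions < 3) stop("need at least 3 repetitions")
  if (!baseline %in% names(configs)) stop("baseline not among configs")
  rows <- lapply(names(configs), function(nm) {
    times <- vapply(seq_len(repetitions), function(i) {
      unname(system.time(apply_filter(configs[[nm]], segment))["elapsed"])
    }, numeric(1))
    data.frame(filter = nm, mean_s = mean(times),
               median_s = stats::median(times), min_s = min(times),
               max_s = max(times))
  })
  out <- do.call(rbind, rows)
  out$ratio_to_baseline <- out$median_s /
    out$median_s[out$filter == baseline]
  out
}
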