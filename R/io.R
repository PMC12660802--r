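#' Write a record to CSV
#'
#' Comma-separated, '.' decimal, header row; first column `time` in
#' seconds, then one column per lead named after the lead.
#'
#' @param record An [ecg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  n <- ncol(record$signals)
  df <- data.frame(time = (0:(n - 1)) / record$fs)
  for (i in seq_len(nrow(record$signals))) {
    df[[record$lead_names[i]]] <- record$signals[i, ]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a record from CSV
#'
#' Inverse of [write_record_csv()]. The sampling rate is inferred from
#' the time column unless given.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz; `NULL` infers it from the median time
#'   step.
#' @param id Record identifier; defaults to the file name.
#' @return An [ecg_record()] with provenance `"csv"`.
#' @export
read_record_csv <- function(path, fs = NULL, id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("CSV must contain a 'time' column")
  if (is.null(fs)) {
    dt <- stats::median(diff(df$time))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate")
    fs <- 1 / dt
  }
  leads <- setdiff(names(df), "time")
  if (length(leads) == 0) stop("CSV contains no lead columns")
  sig <- t(as.matrix(df[leads]))
  ecg_record(sig, fs = fs, lead_names = leads, provenance = "csv",
             id = if (is.null(id)) basename(path) else id)
}

#' Write a record as a WFDB header/signal pair
#'
#' Minimal WFDB writer: format 16 (16-bit little-endian two's complement,
#' interleaved), one `.hea` header plus one `.dat` signal file. Amplitudes
#' are quantised with the given gain in ADC units per millivolt, so the
#' round-trip error is at most half a quantum (`0.5 / gain` mV).
#'
#' @param record An [ecg_record()].
#' @param record_name Base name for the files.
#' @param dir Output directory.
#' @param gain ADC units per millivolt.
#' @return Base path (without extension), invisibly.
#' @export
write_wfdb <- function(record, record_name, dir = ".", gain = 2000) {
  stopifnot(inherits(record, "ecg_record"))
  n_sig <- nrow(record$signals)
  n <- ncol(record$signals)
  adc <- round(record$signals * 1000 * gain)   # volts -> mV -> adu
  if (any(abs(adc) > 32767)) stop("signal exceeds 16-bit range at this gain")
  base <- file.path(dir, record_name)
  hea <- c(sprintf("%s %d %g %d", record_name, n_sig, record$fs, n),
           sprintf("%s.dat 16 %g/mV 16 0 %d 0 0 %s", record_name, gain,
                   adc[seq_len(n_sig), 1], record$lead_names))
  writeLines(hea, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(as.vector(adc)), con, size = 2, endian = "little")
  invisible(base)
}

#' Read a WFDB record
#'
#' Reads a `.hea`/`.dat` pair in format 16 (the format of the PTB
#' Diagnostic ECG Database) and converts amplitudes to volts using each
#' signal's gain and units (mV, uV or V; WFDB's default of 200 adu/mV is
#' used when the gain field is 0 or absent).
#'
#' @param path Path to the `.hea` file or the record base name.
#' @return An [ecg_record()] with provenance `"wfdb"`.
#' @export
read_wfdb <- function(path) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("header file not found: ", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  head_f <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  record_name <- head_f[1]
  n_sig <- as.integer(head_f[2])
  fs <- if (length(head_f) >= 3) as.numeric(sub("/.*$", "", head_f[3])) else 250
  n_samp <- if (length(head_f) >= 4) as.numeric(head_f[4]) else NA
  sig_lines <- lines[2:(1 + n_sig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    fmt <- sub("x.*$", "", f[2])
    gain_field <- if (length(f) >= 3) f[3] else "200"
    units <- if (grepl("/", gain_field)) sub("^.*/", "", gain_field) else "mV"
    gain <- as.numeric(sub("\\(.*\\)", "", sub("/.*$", "", gain_field)))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    } else {
      0
    }
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else NA
    list(file = f[1], fmt = fmt, gain = gain, units = units,
         baseline = baseline, desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  fmts <- unique(vapply(sigs, `[[`, character(1), "fmt"))
  if (!identical(fmts, "16")) {
    stop("unsupported WFDB signal format: ", paste(fmts, collapse = ","),
         " (only format 16 is supported)")
  }
  dat_file <- file.path(dirname(hea_path), sigs[[1]]$file)
  if (!file.exists(dat_file)) stop("signal file not found: ", dat_file)
  raw_n <- file.size(dat_file) / 2
  con <- file(dat_file, "rb")
  on.exit(close(con))
  vals <- readBin(con, integer(), n = raw_n, size = 2, endian = "little",
                  signed = TRUE)
  n_avail <- length(vals) %/% n_sig
  if (!is.na(n_samp) && n_samp > 0) n_avail <- min(n_avail, n_samp)
  m <- matrix(vals[seq_len(n_avail * n_sig)], nrow = n_sig)
  unit_scale <- function(u) {
    switch(tolower(u), mv = 1e-3, uv = 1e-6, v = 1,
           stop("unsupported amplitude unit: ", u))
  }
  for (i in seq_len(n_sig)) {
    m[i, ] <- (m[i, ] - sigs[[i]]$baseline) / sigs[[i]]$gain
  }
  sig <- m * vapply(sigs, function(s) unit_scale(s$units), numeric(1))
  lead_names <- vapply(seq_len(n_sig), function(i) {
    d <- sigs[[i]]$desc
    if (is.na(d) || !nzchar(d)) paste0("L", i) else d
  }, character(1))
  ecg_record(sig, fs = fs, lead_names = lead_names, provenance = "wfdb",
             id = record_name)
}

#' Catalogue a set of records
#'
#' @param records List of [ecg_record()]s.
#' @return Data frame (one row per record) with `record_id`, `fs`,
#'   `n_leads`, `duration_s` and `source`.
#' @export
dataset_manifest <- function(records) {
  if (inherits(records, "ecg_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    data.frame(record_id = r$id, fs = r$fs, n_leads = nrow(r$signals),
               duration_s = ncol(r$signals) / r$fs,
               source = r$provenance)
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$record_id)) stop("duplicate record ids in manifest")
  out
}

#' Census of record durations
#'
#' Groups the manifest by duration (rounded to 3 decimals) and reports
#' counts, most frequent duration first.
#'
#' @param manifest Data frame with a `duration_s` column (see
#'   [dataset_manifest()]).
#' @return Data frame with columns `duration_s`, `record_count`.
#' @export
duration_census <- function(manifest) {
  stopifnot(is.data.frame(manifest), "duration_s" %in% names(manifest),
            nrow(manifest) >= 1)
  d <- round(manifest$duration_s, 3)
  tab <- table(d)
  out <- data.frame(duration_s = as.numeric(names(tab)),
                    record_count = as.integer(tab))
  out <- out[order(-out$record_count, out$duration_s), ]
  rownames(out) <- NULL
  out
}
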