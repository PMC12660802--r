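# Shared fixtures built in code. The scaled-down benchmark (20 synthetic
# 12-lead records, 10 dB AWGN, all nine filters) is expensive, so it is
# computed once per test run and cached for every test that needs it.

.bench_cache <- new.env(parent = emptyenv())

test_records <- function(n = 20, duration_s = 30, seed_base = 1000) {
  key <- sprintf("recs_%d_%g_%d", n, duration_s, seed_base)
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- lapply(seq_len(n), function(i) {
      generate_ecg(duration_s = duration_s, seed = seed_base + i,
                   id = sprintf("syn-%02d", i))
    })
  }
  .bench_cache[[key]]
}

benchmark_10db <- function() {
  if (is.null(.bench_cache$bench10)) {
    .bench_cache$bench10 <- benchmark_run(test_records(),
                                          noise_conditions = 10, seed = 1)
  }
  .bench_cache$bench10
}

# one clean + one 10 dB-noisy protocol segment from a fixed record
test_segment_pair <- function(seed = 42, lead = "II") {
  rec <- generate_ecg(duration_s = 30, seed = seed)
  noisy_rec <- add_awgn(rec, 10, seed = seed + 1)
  list(clean = extract_segment(rec, lead),
       noisy = extract_segment(noisy_rec, lead))
}
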