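# Shared fixtures built in code.

# Clean (noise-free) synthetic record with a given class sequence.
clean_record <- function(classes, seed = 42, ...) {
  set.seed(seed)
  synth_record(classes, noise_sd = 0, baseline_amp = 0, powerline_amp = 0,
               rr_jitter_sd = 0, ...)
}

# Baseline-corrected segments of a clean record.
clean_segments <- function(classes, seed = 42) {
  rec <- clean_record(classes, seed = seed)
  x <- remove_baseline(rec$signal, rec$fs)
  peaks <- detect_r_peaks(x, rec$fs)
  seg <- segment_beats(x, rec$fs, peaks)
  seg$labels <- pair_labels(peaks, rec$annotations$sample,
                            rec$annotations$aami_class, rec$fs)
  seg$record <- rec
  seg
}

# Small random images in [0, 1] for quick learner tests.
toy_images <- function(n, d, seed = 11) {
  set.seed(seed)
  matrix(runif(n * d), n, d)
}

expect_rel_error_lt <- function(actual, expected, tol) {
  scale <- max(abs(expected), 1e-8)
  expect_lt(max(abs(actual - expected)) / scale, tol)
}
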