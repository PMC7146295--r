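# Shared fixtures, built once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# one clean synthetic record at the analysis rate
clean_record <- function() {
  cached("clean_record", {
    cfg <- simulation_config(n_subjects = 1, beats_per_subject = 60, fs = 500,
                             snr_db = Inf, seed = 3)
    simulate_record(make_morphology(42), cfg, "FIX1")
  })
}

# a small noisy cohort for pipeline tests
noisy_cohort_small <- function() {
  cached("noisy_cohort_small", {
    cfg <- simulation_config(n_subjects = 3, beats_per_subject = 60, fs = 500,
                             snr_db = 10, seed = 17)
    simulate_cohort(cfg)
  })
}

# deterministic synthetic wavelet used by template tests
test_wavelet <- function(fs = 500) {
  t_ms <- (seq_len(round(0.8 * fs)) - 1) * 1000 / fs - 100
  exp(-0.5 * ((t_ms - 120) / 60)^2) * sin(2 * pi * 10 * t_ms / 1000) +
    0.4 * exp(-0.5 * ((t_ms - 320) / 80)^2) * sin(2 * pi * 8 * t_ms / 1000)
}

# maximum correlation between a calibrated template and the true wavelet over
# a generous lag range (the template carries an arbitrary constant phase)
template_truth_cor <- function(tmpl_waveform, w, max_lag = 125L) {
  tw <- wavelet_train(w, 300L, 1000L)
  max(vapply(-max_lag:max_lag, function(l) {
    suppressWarnings(cor(tmpl_waveform, tw[(300 - 50 + l):(300 + 349 + l)]))
  }, numeric(1)), na.rm = TRUE)
}

# build a z-scored trace containing copies of `w` at the given centers
wavelet_train <- function(w, centers_idx, n, pre = 50) {
  x <- numeric(n)
  for (c0 in centers_idx) {
    idx <- (c0 - pre):(c0 - pre + length(w) - 1L)
    x[idx] <- x[idx] + w
  }
  x
}
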