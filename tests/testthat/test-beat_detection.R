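test_that("the detection envelope is the causal convolution of the squared signal", {
  cfg <- detection_config()
  fs <- 500
  # zero input stays zero
  expect_equal(detection_signal(numeric(500), fs, cfg), numeric(500))
  # unit impulse reproduces the FIR coefficients (direct-convolution oracle)
  x <- numeric(600)
  n0 <- 101L
  x[n0] <- 1
  b <- signal::fir1(cfg$M - 1L, cfg$det_cutoff_hz / (fs / 2), type = "low")
  xd <- detection_signal(x, fs, cfg)
  expect_equal(xd[n0:(n0 + cfg$M - 1L)], as.numeric(b), tolerance = 1e-12)
  # squaring makes the envelope quadratic in the input scale
  y <- rnorm(600)
  expect_equal(detection_signal(3 * y, fs, cfg),
               9 * detection_signal(y, fs, cfg), tolerance = 1e-9)
  expect_error(detection_signal(numeric(10), fs, cfg),
               class = "scgkit_length_error")
})

test_that("the adaptive square wave thresholds against trailing-window statistics", {
  cfg <- detection_config(p = 3, k = 2)
  # hand-evaluated case: sample std over {1,1,1} is 0, so only the 10 fires
  x <- c(1, 1, 1, 10, 1, 1, 1)
  sq <- square_wave(x, cfg)
  expect_equal(sq, c(-1, -1, -1, 1, -1, -1, -1))
  # constant input: sigma = 0 and mu = x, equality holds -> +1 after warm-up
  sq_const <- square_wave(rep(2, 50), detection_config(p = 30))
  expect_equal(sq_const[1:30], rep(-1, 30))
  expect_equal(sq_const[31:50], rep(1, 20))
  # a huge k silences any non-constant signal after warm-up
  set.seed(2)
  noisy <- abs(rnorm(300))
  expect_true(all(square_wave(noisy, detection_config(p = 30, k = 1e9)) == -1 |
                    seq_along(noisy) <= 30))
})

test_that("alignment window follows the run-length spread", {
  cfg <- detection_config(s = 3)
  expect_equal(alignment_window(c(80, 80, 80), cfg), 0L)
  expect_equal(alignment_window(c(100, 120, 140), cfg), 60L)  # sd = 20, s = 3
  expect_equal(alignment_window(c(100, 120, 140), detection_config(s = 0)), 0L)
  expect_error(alignment_window(100, cfg),
               class = "scgkit_insufficient_data_error")
})

test_that("candidate search obeys the inter-beat interval rules", {
  fs <- 500
  w <- test_wavelet(fs)
  # regular train every 800 ms
  centers <- seq(1000, by = 400, length.out = 30)
  x <- zscore(wavelet_train(w, centers, 14000) + 1e-6 * sin(1:14000))$xz
  sigs <- detection_signals(x, fs)
  cands <- find_candidates(sigs)
  expect_equal(length(cands$instants), 30L)
  expect_true(all(abs(cands$intervals_ms - 800) < 20))
  # an echo pulse 350 ms after a beat is rejected (interval below 400 ms)
  x_echo <- wavelet_train(w, c(centers, 5000 + 175), 14000)
  sigs_e <- detection_signals(zscore(x_echo + 1e-6 * sin(1:14000))$xz, fs)
  cands_e <- find_candidates(sigs_e)
  expect_true(all(cands_e$intervals_ms >= 400))
  # pulses 2000 ms apart exceed the maximum interval at every k -> failure
  centers_slow <- seq(1000, by = 1000, length.out = 12)
  x_slow <- zscore(wavelet_train(w, centers_slow, 14000) + 1e-6 * sin(1:14000))$xz
  sigs_s <- detection_signals(x_slow, fs)
  expect_error(find_candidates(sigs_s), class = "scgkit_detection_failure")
})

test_that("template calibration recovers a known wavelet", {
  fs <- 500
  w <- test_wavelet(fs)
  n <- 12500
  centers <- seq(1000, by = 425, length.out = 25)
  # 20+ identical noise-free beats: template equals a member up to 1e-9
  x0 <- zscore(wavelet_train(w, centers, n) + 1e-9 * sin(1:n))$xz
  sigs0 <- detection_signals(x0, fs)
  cands0 <- find_candidates(sigs0)
  tmpl0 <- calibrate_template(x0, sigs0, cands0)
  member <- x0[(centers[5] - 50):(centers[5] + 349)]
  lag <- which.max(vapply(-80:80, function(l) {
    seg <- tmpl0$waveform
    cor(seg, x0[(centers[5] - 50 + l):(centers[5] + 349 + l)])
  }, numeric(1)))
  best <- (-80:80)[lag]
  expect_gt(cor(tmpl0$waveform,
                x0[(centers[5] - 50 + best):(centers[5] + 349 + best)]), 1 - 1e-9)
  # shifted noisy copies: correlation with the truth >= 0.99
  set.seed(4)
  shifts <- sample(-20:20, 25, replace = TRUE)
  xn <- wavelet_train(w, centers + shifts, n) + rnorm(n, 0, 0.1)
  xn <- zscore(xn)$xz
  sigs_n <- detection_signals(xn, fs)
  tmpl_n <- calibrate_template(xn, sigs_n, find_candidates(sigs_n))
  expect_gt(template_truth_cor(tmpl_n$waveform, w), 0.99)
  # one corrupted beat (beat-scale energy, wrong morphology) is suppressed by
  # the median
  xc <- wavelet_train(w, centers, n)
  span <- (centers[10] - 50):(centers[10] + 349)
  xc[span] <- rev(w) * 1.2
  xc <- zscore(xc + 1e-9 * sin(1:n))$xz
  sigs_c <- detection_signals(xc, fs)
  tmpl_c <- calibrate_template(xc, sigs_c, find_candidates(sigs_c))
  expect_gt(template_truth_cor(tmpl_c$waveform, w), 0.99)
  # too few candidates fail loudly
  short <- zscore(wavelet_train(w, centers[1:5], 4000) + 1e-9 * sin(1:4000))$xz
  sigs_f <- detection_signals(short, fs)
  expect_error(calibrate_template(short, sigs_f, find_candidates(sigs_f)),
               class = "scgkit_calibration_failure")
})

test_that("end-to-end annotation matches generator truth on a clean record", {
  sr <- clean_record()
  det <- detect_and_annotate(sr$record)
  expect_equal(nrow(det$annotations), length(sr$truth_beats_s))
  # constant template phase offset aside, instants track truth within 1 sample
  d <- vapply(det$annotations$time_s, function(t) {
    t - sr$truth_beats_s[which.min(abs(t - sr$truth_beats_s))]
  }, numeric(1))
  expect_lt(max(abs(d - median(d))) * det$fs, 1 + 1e-9)
  # C-C intervals agree with the truth intervals
  expect_lt(sqrt(mean((diff(det$annotations$time_s) - diff(sr$truth_beats_s))^2)) * 500,
            1 + 1e-9)
})

test_that("detection is deterministic, translation-equivariant and amplitude-invariant", {
  sr <- clean_record()
  det1 <- detect_and_annotate(sr$record)
  det2 <- detect_and_annotate(sr$record)
  expect_identical(det1$annotations$instant_idx, det2$annotations$instant_idx)
  # scaling the raw SCG leaves annotations unchanged
  rec_scaled <- scg_record(list(SCG = 7.3 * sr$record$samples$SCG),
                           fs = sr$record$fs, subject_id = "scaled")
  det3 <- detect_and_annotate(rec_scaled)
  expect_identical(det1$annotations$instant_idx, det3$annotations$instant_idx)
  # shifting the input by 10 samples shifts every annotation by 10
  shift <- 10L
  x <- sr$record$samples$SCG
  rec_shift <- scg_record(list(SCG = c(rep(0, shift), x[1:(length(x) - shift)])),
                          fs = sr$record$fs, subject_id = "shifted")
  det4 <- detect_and_annotate(rec_shift)
  n_common <- min(nrow(det1$annotations), nrow(det4$annotations))
  expect_true(all(abs(det4$annotations$instant_idx[1:n_common] -
                        det1$annotations$instant_idx[1:n_common] - shift) <= 1))
})

test_that("refinement never moves an instant beyond the alignment search window", {
  sr <- clean_record()
  det <- detect_and_annotate(sr$record)
  cands <- det$candidates$instants
  for (t_idx in det$annotations$instant_idx) {
    expect_lte(min(abs(t_idx - cands)), det$template$tau_search)
  }
})

test_that("degenerate inputs raise detection errors", {
  rec <- scg_record(list(SCG = rnorm(100)), fs = 500)
  expect_error(detect_and_annotate(rec), class = "scgkit_length_error")
  sr <- clean_record()
  cfg20 <- detection_config(k = 20, allow_k_halving = FALSE)
  # a huge fixed k misses most beats: too few candidates to calibrate
  expect_error(detect_and_annotate(sr$record, cfg20),
               class = c("scgkit_calibration_failure"))
})

test_that("annotations survive a TSV round-trip with 0-based indices on disk", {
  sr <- clean_record()
  det <- detect_and_annotate(sr$record)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(det$annotations, path)
  first <- read.table(path, header = TRUE, sep = "\t", nrows = 1)
  expect_equal(first$sample_index, det$annotations$instant_idx[1] - 1L)
  back <- read_annotations(path, fs = det$fs)
  expect_equal(back$instant_idx, det$annotations$instant_idx)
  expect_equal(back$time_s, det$annotations$time_s, tolerance = 1e-6)
})
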