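#' Beat-detection configuration
#'
#' Parameters of the unsupervised SCG beat detector: the energy-envelope
#' detection signal, the adaptive sliding-window square wave, the candidate
#' acceptance rules, and the template calibration.
#'
#' @param k threshold multiplier on the sliding-window standard deviation
#'   (default 2, the value that maximizes detection F1).
#' @param p sliding-window length in samples for the adaptive threshold
#'   (default 30).
#' @param M length of the envelope low-pass FIR (default 256 taps).
#' @param det_cutoff_hz cutoff of the envelope low-pass (default 2 Hz).
#' @param min_ibi_ms,max_ibi_ms accepted inter-beat interval range in ms
#'   (defaults 400 and 1500, i.e. 40-150 bpm).
#' @param max_rel_var maximum relative variation between consecutive
#'   inter-beat intervals (default 0.30).
#' @param n_ens number of beats in the calibration ensemble (default 20).
#' @param s multiplier on the positive-run-length spread that sets the
#'   cross-correlation alignment half-window tau_s (default 3).
#' @param k_min smallest k before the adaptive search gives up (default 0.25,
#'   three halvings from the default k = 2).
#' @param tau_min_ms floor on the cross-correlation search half-window in ms
#'   (default 80): the template search must at least span the width over
#'   which a noisy, flat-topped detection envelope can displace a candidate,
#'   even when the run-length spread (and hence tau_s) is small.
#' @param min_run_ms positive square-wave runs shorter than this are treated
#'   as rebounds and discarded (default 40 ms).
#' @param allow_k_halving retry with k/2 when an interval exceeds
#'   `max_ibi_ms` (default TRUE; disable to scan fixed k values).
#' @param template_pre_ms,template_post_ms template/beat window extent around
#'   the anchor instant (defaults 100 before, 700 after; the segmentation
#'   window uses the same convention).
#' @return a `detection_config` list.
#' @export
detection_config <- function(k = 2, p = 30L, M = 256L, det_cutoff_hz = 2,
                             min_ibi_ms = 400, max_ibi_ms = 1500,
                             max_rel_var = 0.30, n_ens = 20L, s = 3,
                             k_min = 0.25, min_run_ms = 40,
                             allow_k_halving = TRUE, tau_min_ms = 80,
                             template_pre_ms = 100, template_post_ms = 700) {
  assert_scalar_number(k, "k", min = .Machine$double.eps)
  assert_scalar_number(p, "p", min = 2)
  assert_scalar_number(M, "M", min = 2)
  assert_scalar_number(min_ibi_ms, "min_ibi_ms", min = .Machine$double.eps)
  assert_scalar_number(max_ibi_ms, "max_ibi_ms", min = min_ibi_ms)
  assert_scalar_number(max_rel_var, "max_rel_var", min = 1e-12, max = 1 - 1e-12)
  assert_scalar_number(n_ens, "n_ens", min = 2)
  assert_scalar_number(s, "s", min = 0)
  structure(list(k = k, p = as.integer(p), M = as.integer(M),
                 det_cutoff_hz = det_cutoff_hz, min_ibi_ms = min_ibi_ms,
                 max_ibi_ms = max_ibi_ms, max_rel_var = max_rel_var,
                 n_ens = as.integer(n_ens), s = s, k_min = k_min,
                 min_run_ms = min_run_ms, allow_k_halving = allow_k_halving,
                 tau_min_ms = tau_min_ms,
                 template_pre_ms = template_pre_ms,
                 template_post_ms = template_post_ms),
            class = "detection_config")
}

#' Energy-envelope detection signal
#'
#' Causal convolution of the squared z-scored SCG with an `M`-tap low-pass FIR
#' (Hamming windowed-sinc, cutoff `det_cutoff_hz`): a smooth envelope of local
#' signal energy whose maxima mark heartbeat complexes.
#'
#' @param xz z-scored SCG samples.
#' @param fs sampling rate in Hz.
#' @param cfg a [detection_config()].
#' @return numeric envelope, same length as `xz`.
#' @export
detection_signal <- function(xz, fs, cfg = detection_config()) {
  if (length(xz) < cfg$M) {
    abort(sprintf("signal shorter than the detection FIR (%d samples)", cfg$M),
          class = "scgkit_length_error")
  }
  b <- signal::fir1(cfg$M - 1L, cfg$det_cutoff_hz / (fs / 2), type = "low")
  fir_causal(xz^2, b)
}

#' Adaptive-threshold square wave
#'
#' Marks each envelope sample +1 when it stands out against the trailing
#' window statistics (`x_det[i] >= mu + k * sigma` over the previous `p`
#' samples, sample standard deviation), -1 otherwise. The first `p` samples
#' are -1 (warm-up: the trailing window is not yet defined).
#'
#' @param x_det detection envelope from [detection_signal()].
#' @param cfg a [detection_config()].
#' @param k optional override of `cfg$k` (used by the adaptive halving).
#' @return numeric vector of +1/-1, same length as `x_det`.
#' @export
square_wave <- function(x_det, cfg = detection_config(), k = NULL) {
  p <- cfg$p
  k <- k %||% cfg$k
  n <- length(x_det)
  if (n < p + 1L) {
    abort(sprintf("signal shorter than the sliding window (p = %d)", p),
          class = "scgkit_length_error")
  }
  out <- rep(-1, n)
  S1 <- c(0, cumsum(x_det))
  S2 <- c(0, cumsum(x_det^2))
  i <- (p + 1L):n
  w_sum <- S1[i] - S1[i - p]          # samples i-p ... i-1
  w_sum2 <- S2[i] - S2[i - p]
  mu <- w_sum / p
  v <- pmax((w_sum2 - p * mu^2) / (p - 1), 0)
  thr <- mu + k * sqrt(v)
  out[i] <- ifelse(x_det[i] >= thr - 1e-12 * pmax(1, abs(thr)), 1, -1)
  out
}

#' Detection signals for one record
#'
#' Computes the envelope and its adaptive square wave in one step.
#'
#' @inheritParams detection_signal
#' @return a `detection_signals` list with `x_det`, `x_sqr`, `fs`, `cfg`.
#' @export
detection_signals <- function(xz, fs, cfg = detection_config()) {
  x_det <- detection_signal(xz, fs, cfg)
  structure(list(x_det = x_det, x_sqr = square_wave(x_det, cfg), fs = fs,
                 k = cfg$k),
            class = "detection_signals")
}

positive_runs <- function(x_sqr, min_len) {
  r <- rle(x_sqr > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  cbind(start = starts[keep], end = ends[keep])
}

#' Candidate heartbeat instants
#'
#' Finds positive square-wave runs (discarding short rebounds), takes the
#' envelope maximum around each surviving run as a candidate instant, and
#' enforces the inter-beat interval rules: intervals must lie in
#' `[min_ibi_ms, max_ibi_ms]` with relative variation below `max_rel_var`.
#' Candidates closer than `min_ibi_ms` to their predecessor are treated as
#' echoes and dropped (the weaker envelope peak loses). If any interval still
#' exceeds `max_ibi_ms`, the square wave is recomputed with `k/2` and the
#' search repeats, failing once `k < k_min`.
#'
#' @param sigs a [detection_signals()] object.
#' @param cfg a [detection_config()].
#' @return a `candidate_beats` list: `instants` (sample indices),
#'   `intervals_ms`, `k_used`, `run_lengths` (samples), `fs`.
#' @export
find_candidates <- function(sigs, cfg = detection_config()) {
  stopifnot(inherits(sigs, "detection_signals"))
  fs <- sigs$fs
  min_run <- max(1L, round(cfg$min_run_ms * fs / 1000))
  k <- cfg$k
  x_sqr <- sigs$x_sqr
  repeat {
    res <- candidates_once(sigs$x_det, x_sqr, fs, min_run, cfg)
    too_long <- length(res$intervals_ms) > 0 &&
      any(res$intervals_ms > cfg$max_ibi_ms)
    if (!too_long || !cfg$allow_k_halving) break
    k <- k / 2
    if (k < cfg$k_min) {
      abort(sprintf(paste0("beat detection failed: intervals above %g ms ",
                           "persist down to k = %g (max interval %.0f ms, ",
                           "%d candidates)"),
                    cfg$max_ibi_ms, k * 2, max(res$intervals_ms),
                    length(res$instants)),
            class = "scgkit_detection_failure")
    }
    x_sqr <- square_wave(sigs$x_det, cfg, k = k)
  }
  structure(c(res, list(k_used = k, fs = fs)), class = "candidate_beats")
}

candidates_once <- function(x_det, x_sqr, fs, min_run, cfg) {
  runs <- positive_runs(x_sqr, min_run)
  n <- length(x_det)
  if (nrow(runs) == 0L) {
    return(list(instants = integer(0), intervals_ms = numeric(0),
                run_lengths = integer(0)))
  }
  # locate the envelope maximum around each run, then take the centroid of
  # the surrounding above-half-maximum hump: on flat-topped or rippled
  # envelope peaks the bare argmax scatters with noise while the hump
  # centroid stays put. Instants are mapped back to signal time by the causal
  # FIR group delay ((M-1)/2 samples of the linear-phase low-pass).
  gd <- (cfg$M - 1L) %/% 2L
  half_max_span <- round(0.5 * fs)   # bound the hump walk to half a second
  located <- vapply(seq_len(nrow(runs)), function(i) {
    a <- max(1L, runs[i, "start"] - cfg$p)
    b <- min(n, runs[i, "end"] + cfg$p)
    pk_i <- (a:b)[which.max(x_det[a:b])]
    pk <- x_det[pk_i]
    lo <- pk_i
    while (lo > 1L && x_det[lo - 1L] > 0.5 * pk && pk_i - lo < half_max_span) lo <- lo - 1L
    hi <- pk_i
    while (hi < n && x_det[hi + 1L] > 0.5 * pk && hi - pk_i < half_max_span) hi <- hi + 1L
    w <- x_det[lo:hi] - 0.5 * pk
    c(round(sum((lo:hi) * w) / sum(w)), pk)
  }, numeric(2))
  ord <- order(located[1, ])
  inst <- as.integer(located[1, ord])
  strength <- located[2, ord]
  dup <- duplicated(inst)
  inst <- inst[!dup]
  strength <- strength[!dup]
  inst <- inst - gd
  strength <- strength[inst >= 1L]
  inst <- inst[inst >= 1L]
  # residual-rebound gate: envelope maxima far below the typical detected
  # magnitude are noise bumps that slipped past the local threshold
  if (length(inst) >= 5L) {
    keep <- strength >= 0.25 * median(strength)
    inst <- inst[keep]
    strength <- strength[keep]
  }
  min_gap <- cfg$min_ibi_ms * fs / 1000
  # echo suppression: of two candidates closer than the minimum interval,
  # keep the stronger envelope peak
  i <- 2L
  while (i <= length(inst)) {
    if (inst[i] - inst[i - 1L] < min_gap) {
      drop <- if (strength[i] >= strength[i - 1L]) i - 1L else i
      inst <- inst[-drop]
      strength <- strength[-drop]
      i <- max(2L, i - 1L)
    } else {
      i <- i + 1L
    }
  }
  # relative-variation rule: remove an interior candidate when its two
  # flanking intervals both deviate beyond max_rel_var from the local median
  # and merging them restores an acceptable interval
  if (length(inst) >= 4L) {
    d <- diff(inst) / fs * 1000
    med <- median(d)
    bad <- which(abs(d - med) / med > cfg$max_rel_var)
    for (j in rev(intersect(bad, bad + 1L))) {   # j-1 and j both flagged
      merged <- (inst[j + 1L] - inst[j - 1L]) / fs * 1000
      if (merged <= cfg$max_ibi_ms && abs(merged - med) / med <= cfg$max_rel_var) {
        inst <- inst[-j]
      }
    }
  }
  list(instants = inst,
       intervals_ms = if (length(inst) > 1L) diff(inst) / fs * 1000 else numeric(0),
       run_lengths = as.integer(runs[, "end"] - runs[, "start"] + 1L))
}

#' Cross-correlation alignment half-window
#'
#' `tau_s = round(s * sd(run_lengths))` where the standard deviation (sample
#' convention) is taken over the positive square-wave run lengths: subjects
#' with more variable envelope bursts get a wider alignment search.
#'
#' @param run_lengths positive-run lengths in samples (>= 2 values).
#' @param cfg a [detection_config()].
#' @return integer half-window in samples.
#' @export
alignment_window <- function(run_lengths, cfg = detection_config()) {
  if (length(run_lengths) < 2L) {
    abort("need >= 2 positive runs to size the alignment window",
          class = "scgkit_insufficient_data_error")
  }
  as.integer(round(cfg$s * sd(run_lengths)))
}

segment_at <- function(xz, center, pre, post) {
  xz[(center - pre):(center + post - 1L)]
}

# Pearson correlation score per candidate lag; ties resolved to the smallest
# absolute lag, then the earliest. `tau` may be a scalar half-window or an
# explicit integer lag set.
best_lag <- function(ref, xz, center, pre, post, tau, n) {
  lags <- if (length(tau) > 1L) tau else (-tau):tau
  lags <- lags[center + lags - pre >= 1L & center + lags + post - 1L <= n]
  if (length(lags) == 0L) return(NA_integer_)
  ord <- order(abs(lags), lags)
  lags <- lags[ord]
  scores <- vapply(lags, function(l) {
    seg <- segment_at(xz, center + l, pre, post)
    if (sd(seg) == 0 || sd(ref) == 0) return(-Inf)
    stats::cor(ref, seg)
  }, numeric(1))
  lags[which.max(scores)]   # first max in (|lag|, lag) order
}

#' Calibrate the per-subject beat template
#'
#' Takes the first `n_ens` candidate beats, centers each on its envelope
#' maximum, incrementally aligns them (each new beat is shifted by the lag in
#' `[-tau_s, tau_s]` that maximizes Pearson cross-correlation with the running
#' pointwise median of the already-aligned ensemble), and returns the
#' pointwise median waveform.
#'
#' @param xz z-scored SCG samples.
#' @param sigs the [detection_signals()] for `xz`.
#' @param cands [find_candidates()] output.
#' @param cfg a [detection_config()].
#' @return a `beat_template`: `waveform`, `tau_s`, `sigma_sqr`, `anchor`
#'   (index of the centering instant inside the waveform), `fs`.
#' @export
calibrate_template <- function(xz, sigs, cands, cfg = detection_config()) {
  fs <- sigs$fs
  pre <- round(cfg$template_pre_ms * fs / 1000)
  post <- round(cfg$template_post_ms * fs / 1000)
  sigma_sqr <- if (length(cands$run_lengths) >= 2L) sd(cands$run_lengths) else 0
  if (length(cands$run_lengths) < 2L) {
    abort("calibration needs at least two positive envelope runs",
          class = "scgkit_calibration_failure")
  }
  tau_s <- alignment_window(cands$run_lengths, cfg)
  tau <- max(tau_s, as.integer(round(cfg$tau_min_ms * fs / 1000)))
  n <- length(xz)
  ok <- cands$instants - pre - tau >= 1L & cands$instants + post - 1L + tau <= n
  inst <- cands$instants[ok]
  if (length(inst) < cfg$n_ens) {
    abort(sprintf("calibration needs %d candidate beats, found %d",
                  cfg$n_ens, length(inst)),
          class = "scgkit_calibration_failure")
  }
  inst <- inst[seq_len(cfg$n_ens)]
  members <- matrix(0, nrow = pre + post, ncol = cfg$n_ens)
  centers <- as.numeric(inst)
  for (j in seq_along(inst)) {
    center <- inst[[j]]
    if (j > 1L && tau > 0L) {
      ref <- if (j == 2L) members[, 1L] else
        apply(members[, seq_len(j - 1L), drop = FALSE], 1, median)
      lag <- best_lag(ref, xz, center, pre, post, tau, n)
      if (!is.na(lag)) center <- center + lag
    }
    members[, j] <- segment_at(xz, center, pre, post)
    centers[j] <- center
  }
  # re-align the whole ensemble to the evolving median template: removes the
  # order dependence of the incremental pass and suppresses members that
  # locked on one oscillation cycle off
  for (pass in 1:2) {
    if (tau == 0L) break
    tmpl <- apply(members, 1, median)
    for (j in seq_along(inst)) {
      lag <- best_lag(tmpl, xz, inst[[j]], pre, post, tau, n)
      if (!is.na(lag)) {
        centers[j] <- inst[[j]] + lag
        members[, j] <- segment_at(xz, centers[j], pre, post)
      }
    }
  }
  structure(list(waveform = apply(members, 1, median), tau_s = tau_s,
                 tau_search = tau, sigma_sqr = sigma_sqr, anchor = pre + 1L,
                 fs = fs, pre = pre, post = post),
            class = "beat_template")
}

#' @export
print.beat_template <- function(x, ...) {
  cat(sprintf("<beat_template> %d samples @ %g Hz, anchor %d, tau_s %d\n",
              length(x$waveform), x$fs, x$anchor, x$tau_s))
  invisible(x)
}

#' Annotate heartbeat instants on a full record
#'
#' Re-runs the candidate search, then refines every candidate by the lag in
#' `[-tau_s, tau_s]` that maximizes cross-correlation between the calibrated
#' template and the signal; the maximal-alignment point is the heartbeat
#' instant. Candidates whose beat window leaves the record are dropped.
#'
#' @param xz z-scored SCG samples.
#' @param sigs the [detection_signals()] for `xz`.
#' @param tmpl a [calibrate_template()] result.
#' @param cfg a [detection_config()].
#' @return a tibble of class `scg_annotations` with columns `beat`,
#'   `instant_idx` (1-based sample index) and `time_s`; attributes `fs` and
#'   `k_used`.
#' @export
annotate_beats <- function(xz, sigs, tmpl, cfg = detection_config()) {
  stopifnot(inherits(tmpl, "beat_template"))
  cands <- find_candidates(sigs, cfg)
  n <- length(xz)
  lags <- vapply(cands$instants, function(c0) {
    as.integer(best_lag(tmpl$waveform, xz, c0, tmpl$pre, tmpl$post,
                        tmpl$tau_search, n) %||% NA_integer_)
  }, integer(1))
  # consensus pass: the template-to-beat lag has a stable subject-specific
  # component; re-anchoring each beat near the median lag removes the
  # one-oscillation-cycle ambiguity of the free cross-correlation search
  if (sum(is.finite(lags)) >= 3L && tmpl$tau_search > 0L) {
    lam <- as.integer(round(median(lags, na.rm = TRUE)))
    half <- as.integer(round(0.045 * sigs$fs))
    lag_set <- intersect((lam - half):(lam + half), (-tmpl$tau_search):tmpl$tau_search)
    if (length(lag_set)) {
      lags <- vapply(cands$instants, function(c0) {
        as.integer(best_lag(tmpl$waveform, xz, c0, tmpl$pre, tmpl$post,
                            lag_set, n) %||% NA_integer_)
      }, integer(1))
    }
  }
  inst <- sort(unique(cands$instants[is.finite(lags)] + lags[is.finite(lags)]))
  new_annotations(inst, sigs$fs, k_used = cands$k_used)
}

new_annotations <- function(instants_idx, fs, k_used = NA_real_) {
  out <- tibble(beat = seq_along(instants_idx),
                instant_idx = as.integer(instants_idx),
                time_s = (instants_idx - 1) / fs)
  class(out) <- c("scg_annotations", class(out))
  attr(out, "fs") <- fs
  attr(out, "k_used") <- k_used
  out
}

#' Inter-beat (C-C) intervals of an annotation set
#'
#' @param ann an `scg_annotations` tibble (or any vector of beat times in s).
#' @return numeric vector of successive intervals in ms.
#' @export
cc_intervals_ms <- function(ann) {
  t_s <- if (is.data.frame(ann)) ann$time_s else as.numeric(ann)
  diff(t_s) * 1000
}

#' Detect and annotate heartbeats end-to-end
#'
#' Full unsupervised pipeline on one record: preprocess the SCG channel
#' (resample to `fs_target`, zero-phase 1-20 Hz bandpass, z-score), compute
#' the detection signals, find candidates, calibrate the subject template,
#' and annotate every beat. Deterministic given the record and configuration;
#' no ECG is used at any step.
#'
#' @param rec an [scg_record()].
#' @param cfg a [detection_config()].
#' @param channel SCG channel name/index (default: auto-detect by name).
#' @param fs_target analysis sampling rate (default 500 Hz).
#' @param band SCG passband in Hz (default `c(1, 20)`).
#' @return an `scg_detection` object: `annotations` (tibble), `template`,
#'   `candidates`, `signals`, `config`, `subject_id`, `fs`.
#' @export
detect_and_annotate <- function(rec, cfg = detection_config(), channel = NULL,
                                fs_target = 500, band = c(1, 20)) {
  stopifnot(inherits(rec, "scg_record"))
  x <- record_channel(rec, channel)
  pp <- preprocess_channel(x, rec$fs, fs_target = fs_target, band = band)
  sigs <- detection_signals(pp$xz, pp$fs, cfg)
  cands <- find_candidates(sigs, cfg)
  tmpl <- calibrate_template(pp$xz, sigs, cands, cfg)
  ann <- annotate_beats(pp$xz, sigs, tmpl, cfg)
  structure(list(annotations = ann, template = tmpl, candidates = cands,
                 signals = sigs, xz = pp$xz, config = cfg,
                 subject_id = rec$subject_id, fs = pp$fs),
            class = "scg_detection")
}

#' @export
print.scg_detection <- function(x, ...) {
  iv <- cc_intervals_ms(x$annotations)
  cat(sprintf("<scg_detection> subject=%s: %d beats @ %g Hz (k_used=%g)\n",
              x$subject_id, nrow(x$annotations), x$fs, x$candidates$k_used))
  if (length(iv)) {
    cat(sprintf("  C-C intervals: mean %.1f ms, sd %.1f ms\n", mean(iv), sd(iv)))
  }
  invisible(x)
}

#' @rdname detect_and_annotate
#' @param x an `scg_detection` object.
#' @param ... unused.
#' @export
tidy.scg_detection <- function(x, ...) {
  out <- x$annotations
  out$subject_id <- x$subject_id
  as_tibble(out)
}

#' @rdname detect_and_annotate
#' @export
glance.scg_detection <- function(x, ...) {
  iv <- cc_intervals_ms(x$annotations)
  tibble(subject_id = x$subject_id, n_beats = nrow(x$annotations),
         k_used = x$candidates$k_used, tau_s = x$template$tau_s,
         mean_cc_ms = if (length(iv)) mean(iv) else NA_real_,
         sd_cc_ms = if (length(iv) > 1) sd(iv) else NA_real_)
}

#' Write / read beat annotations as TSV
#'
#' Two-column TSV (`sample_index`, `time_s`); `sample_index` is 0-based on
#' disk so that `time_s = sample_index / fs`.
#'
#' @param ann an `scg_annotations` tibble.
#' @param path output path.
#' @return `path` (writer) or an `scg_annotations` tibble (reader).
#' @export
write_annotations <- function(ann, path) {
  df <- data.frame(sample_index = ann$instant_idx - 1L,
                   time_s = sprintf("%.6f", ann$time_s))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @param fs sampling rate in Hz used to rebuild in-memory 1-based indices.
#' @export
read_annotations <- function(path, fs) {
  df <- read.table(path, header = TRUE, sep = "\t")
  new_annotations(df$sample_index + 1L, fs)
}
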