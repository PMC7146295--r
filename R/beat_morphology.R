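#' Segment annotated beats into fixed-length scaled vectors
#'
#' Per annotated beat: crop the z-scored SCG from 100 ms before to 700 ms
#' after the instant (400 samples at 500 Hz), downsample by 2 to 200 samples,
#' saturate to the +/-5 range, and add an offset of 5 so the network input
#' lies in 0-10. Beats whose window leaves the record are dropped.
#'
#' @param xz z-scored SCG samples (analysis rate).
#' @param fs sampling rate in Hz; must yield 400 raw samples per 800 ms
#'   window (i.e. 500 Hz).
#' @param ann an `scg_annotations` tibble (or vector of 1-based instants).
#' @param subject_id label attached to every row.
#' @return a `heartbeat_matrix`: `segments` (n x 200 matrix in [0, 10]),
#'   `subject_ids`, `beat_times_s`.
#' @export
segment_heartbeats <- function(xz, fs, ann, subject_id = NA_character_) {
  pre <- round(0.1 * fs)
  post <- round(0.7 * fs)
  if (pre + post != 400L) {
    abort("beat segmentation requires an 800 ms window of 400 samples (fs = 500 Hz)",
          class = "scgkit_argument_error")
  }
  inst <- if (is.data.frame(ann)) ann$instant_idx else as.integer(ann)
  n <- length(xz)
  keep <- inst - pre >= 1L & inst + post - 1L <= n
  inst <- inst[keep]
  segs <- matrix(numeric(0), nrow = 0, ncol = 200)
  if (length(inst)) {
    segs <- t(vapply(inst, function(i) {
      raw <- xz[(i - pre):(i + post - 1L)]
      pmin(pmax(raw[seq(1L, 400L, by = 2L)], -5), 5) + 5
    }, numeric(200)))
  }
  heartbeat_matrix(segs, rep(subject_id, length(inst)), (inst - 1) / fs)
}

#' Heartbeat matrix container
#'
#' @param segments n x 200 numeric matrix of scaled beat segments in [0, 10].
#' @param subject_ids per-row subject label.
#' @param beat_times_s per-row annotation time in seconds.
#' @return a `heartbeat_matrix` object.
#' @export
heartbeat_matrix <- function(segments, subject_ids, beat_times_s = rep(NA_real_, nrow(segments))) {
  segments <- as.matrix(segments)
  if (nrow(segments) > 0 && ncol(segments) != 200L) {
    abort("segments must have exactly 200 columns", class = "scgkit_shape_error")
  }
  if (nrow(segments) > 0 && (min(segments) < 0 || max(segments) > 10)) {
    abort("segment values must lie in [0, 10]", class = "scgkit_format_error")
  }
  if (length(subject_ids) != nrow(segments) || length(beat_times_s) != nrow(segments)) {
    abort("per-row labels must match the number of segments",
          class = "scgkit_shape_error")
  }
  structure(list(segments = segments, subject_ids = as.character(subject_ids),
                 beat_times_s = as.numeric(beat_times_s)),
            class = "heartbeat_matrix")
}

#' @export
print.heartbeat_matrix <- function(x, ...) {
  cat(sprintf("<heartbeat_matrix> %d beats x 200 samples, %d subject(s)\n",
              nrow(x$segments), length(unique(x$subject_ids))))
  invisible(x)
}

#' @export
as_tibble.heartbeat_matrix <- function(x, ...) {
  tibble(subject_id = x$subject_ids, beat_time_s = x$beat_times_s,
         segment = lapply(seq_len(nrow(x$segments)), function(i) x$segments[i, ]))
}

#' Combine heartbeat matrices (e.g. across subjects)
#'
#' @param ... `heartbeat_matrix` objects, or a single list of them.
#' @return a single `heartbeat_matrix`.
#' @export
bind_heartbeats <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "heartbeat_matrix")) xs <- xs[[1]]
  heartbeat_matrix(do.call(rbind, lapply(xs, `[[`, "segments")),
                   unlist(lapply(xs, `[[`, "subject_ids")),
                   unlist(lapply(xs, `[[`, "beat_times_s")))
}

#' Segment every record of a cohort with its own detection run
#'
#' Runs [detect_and_annotate()] per record and stacks the segmented beats.
#'
#' @param records list of [scg_record()]s or `synthetic_record`s.
#' @param cfg a [detection_config()].
#' @param fs_target analysis rate (default 500 Hz).
#' @return a `heartbeat_matrix` with per-subject labels.
#' @export
segment_cohort <- function(records, cfg = detection_config(), fs_target = 500) {
  mats <- lapply(records, function(r) {
    rec <- if (inherits(r, "synthetic_record")) r$record else r
    det <- detect_and_annotate(rec, cfg, fs_target = fs_target)
    segment_heartbeats(det$xz, det$fs, det$annotations, rec$subject_id)
  })
  bind_heartbeats(mats)
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form `0.5 * sum(mu^2 + exp(log_var) - 1 - log_var)`, the smoothness
#' regularizer that drives the approximate posterior towards the N(0, I)
#' prior.
#'
#' @param mu mean vector.
#' @param log_var log-variance vector (same length).
#' @return scalar >= 0.
#' @export
kl_gaussian <- function(mu, log_var) {
  stopifnot(length(mu) == length(log_var), all(is.finite(mu)), all(is.finite(log_var)))
  0.5 * sum(mu^2 + exp(log_var) - 1 - log_var)
}

#' Write / read a heartbeat matrix as TSV
#'
#' Plain-text persistence: columns `subject_id`, `beat_time_s`, then the 200
#' segment samples `s001`..`s200`.
#'
#' @param beats a [heartbeat_matrix()].
#' @param path file path.
#' @return `path` (writer) / a `heartbeat_matrix` (reader).
#' @export
write_heartbeats <- function(beats, path) {
  df <- data.frame(subject_id = beats$subject_ids,
                   beat_time_s = beats$beat_times_s,
                   beats$segments, check.names = FALSE)
  names(df)[-(1:2)] <- sprintf("s%03d", 1:200)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_heartbeats
#' @export
read_heartbeats <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  heartbeat_matrix(as.matrix(df[, -(1:2)]), df$subject_id, df$beat_time_s)
}
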