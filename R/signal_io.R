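#' Multichannel physiological record
#'
#' Container for a uniformly sampled multichannel record (e.g. an SCG
#' accelerometer trace plus reference ECG leads). All channels share one
#' sampling rate and length.
#'
#' @param samples named list of equal-length numeric vectors, one per channel
#'   (names are channel labels such as `"SCG"`, `"ECG-I"`).
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id opaque subject identifier.
#'
#' @return An object of class `scg_record` with elements `samples`, `fs`,
#'   `channel_names`, `subject_id`, `n`.
#' @export
scg_record <- function(samples, fs, subject_id = NA_character_) {
  if (!is.list(samples) || length(samples) == 0L) {
    abort("`samples` must be a non-empty named list of numeric vectors",
          class = "scgkit_format_error")
  }
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("ch", seq_along(samples))
  }
  lens <- vapply(samples, length, integer(1))
  if (length(unique(lens)) != 1L) {
    abort("all channels must have equal length", class = "scgkit_format_error")
  }
  if (lens[[1]] < 1L) {
    abort("channels must contain at least one sample", class = "scgkit_format_error")
  }
  assert_scalar_number(fs, "fs", min = .Machine$double.eps)
  structure(
    list(samples = lapply(samples, as.numeric), fs = as.numeric(fs),
         channel_names = names(samples), subject_id = subject_id,
         n = unname(lens[[1]])),
    class = "scg_record"
  )
}

#' @export
print.scg_record <- function(x, ...) {
  cat(sprintf("<scg_record> subject=%s  fs=%g Hz  n=%d (%.1f s)\n",
              x$subject_id, x$fs, x$n, x$n / x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_tibble.scg_record <- function(x, ...) {
  tibble(time_s = (seq_len(x$n) - 1) / x$fs, !!!x$samples)
}

#' Extract one channel of a record
#'
#' @param rec an [scg_record()].
#' @param channel channel name or index; by default the first channel whose
#'   name contains `"SCG"` (case-insensitive), else the first channel.
#' @return numeric vector of samples.
#' @export
record_channel <- function(rec, channel = NULL) {
  stopifnot(inherits(rec, "scg_record"))
  if (is.null(channel)) {
    hit <- grep("scg", rec$channel_names, ignore.case = TRUE)
    channel <- if (length(hit)) hit[[1]] else 1L
  }
  if (is.character(channel) && !channel %in% rec$channel_names) {
    abort(sprintf("channel '%s' not found", channel), class = "scgkit_argument_error")
  }
  rec$samples[[channel]]
}

#' Read a record from disk
#'
#' Reads either a WFDB record (PhysioNet `.hea`/`.dat` pair, format 16) or a
#' plain CSV file with one column per channel and a header row of channel
#' names. CSV carries no sampling rate, so `fs` must be supplied (or a sidecar
#' YAML `<path>.yml` with an `fs:` entry must exist).
#'
#' @param path for WFDB, the record base path (with or without `.hea`); for
#'   CSV, the file path.
#' @param format `"auto"` (default, by extension), `"wfdb"` or `"csv"`.
#' @param fs sampling rate in Hz; required for CSV without sidecar.
#' @param subject_id optional subject label (defaults to the file base name).
#' @return an [scg_record()].
#' @export
read_record <- function(path, format = c("auto", "wfdb", "csv"), fs = NULL,
                        subject_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  subject_id <- subject_id %||% sub("\\.(csv|hea|dat)$", "", basename(path))
  if (format == "csv") {
    if (!file.exists(path)) {
      abort(sprintf("file not found: %s", path), class = "scgkit_io_error")
    }
    if (is.null(fs)) {
      sidecar <- paste0(path, ".yml")
      if (file.exists(sidecar)) {
        fs <- yaml::read_yaml(sidecar)$fs
      }
    }
    if (is.null(fs)) {
      abort("CSV records need `fs` (argument or '<path>.yml' sidecar)",
            class = "scgkit_argument_error")
    }
    nf <- utils::count.fields(path, sep = ",")
    if (length(unique(nf)) != 1L) {
      abort("ragged CSV: rows have differing column counts",
            class = "scgkit_format_error")
    }
    df <- utils::read.csv(path, check.names = FALSE)
    if (!all(vapply(df, is.numeric, logical(1)))) {
      abort("CSV channels must be numeric", class = "scgkit_format_error")
    }
    scg_record(as.list(df), fs = fs, subject_id = subject_id)
  } else {
    read_wfdb(path, subject_id = subject_id)
  }
}

#' Write a record to disk
#'
#' CSV output preserves samples to full double precision (bit-exact
#' round-trip); WFDB output quantizes to 16-bit integers with a per-channel
#' gain.
#'
#' @param rec an [scg_record()].
#' @param path output path (`.csv` for CSV, otherwise WFDB base path).
#' @param format `"auto"`, `"wfdb"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_record <- function(rec, path, format = c("auto", "wfdb", "csv")) {
  stopifnot(inherits(rec, "scg_record"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (format == "csv") {
    df <- as.data.frame(rec$samples, check.names = FALSE, optional = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(names(df), collapse = ","), con)
    body <- do.call(paste, c(lapply(df, function(v) sprintf("%.17g", v)),
                             sep = ","))
    writeLines(body, con)
    yaml::write_yaml(list(fs = rec$fs), paste0(path, ".yml"))
  } else {
    write_wfdb(rec, path)
  }
  invisible(path)
}

#' FIR filter specification
#'
#' @param low_hz lower passband edge in Hz (0 allowed for lowpass).
#' @param high_hz upper passband edge in Hz.
#' @param numtaps FIR length (odd, >= 3); default 513, sized for sub-Hz
#'   passband edges at a 500 Hz rate.
#' @param kind `"bandpass"` or `"lowpass"`.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(low_hz, high_hz, numtaps = 513L, kind = c("bandpass", "lowpass")) {
  kind <- match.arg(kind)
  assert_scalar_number(low_hz, "low_hz", min = 0)
  assert_scalar_number(high_hz, "high_hz", min = .Machine$double.eps)
  if (low_hz >= high_hz) {
    abort("low_hz must be < high_hz", class = "scgkit_argument_error")
  }
  numtaps <- as.integer(numtaps)
  if (numtaps < 3L || numtaps %% 2L == 0L) {
    abort("numtaps must be odd and >= 3", class = "scgkit_argument_error")
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, numtaps = numtaps,
                 kind = kind), class = "filter_spec")
}

fir_coefficients <- function(spec, fs) {
  if (spec$high_hz >= fs / 2) {
    abort("high_hz must be below the Nyquist frequency fs/2",
          class = "scgkit_argument_error")
  }
  nyq <- fs / 2
  if (spec$kind == "lowpass" || spec$low_hz <= 0) {
    signal::fir1(spec$numtaps - 1L, spec$high_hz / nyq, type = "low")
  } else {
    signal::fir1(spec$numtaps - 1L, c(spec$low_hz, spec$high_hz) / nyq,
                 type = "pass")
  }
}

#' Zero-phase FIR bandpass filtering
#'
#' Applies a windowed-sinc (Hamming) FIR forward and backward so the net group
#' delay is zero: phase relations between channels (e.g. ECG R peaks vs. SCG
#' complexes) are preserved. The signal is extended by odd reflection over
#' `3 * numtaps` samples at each end before filtering to suppress startup
#' transients.
#'
#' @param x numeric samples.
#' @param fs sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return filtered samples, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  npad <- 3L * spec$numtaps
  if (length(x) <= npad) {
    abort(sprintf("signal too short for zero-phase filtering: need > %d samples",
                  npad), class = "scgkit_length_error")
  }
  b <- fir_coefficients(spec, fs)
  n <- length(x)
  left <- 2 * x[1] - x[(npad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(left, x, right)
  y <- fir_causal(fir_causal(xp, b, reverse = FALSE), b, reverse = TRUE)
  y[(npad + 1L):(npad + n)]
}

# Causal FIR convolution; `reverse = TRUE` runs it time-reversed so a
# forward+reverse pair yields zero net phase.
fir_causal <- function(x, b, reverse = FALSE) {
  if (reverse) x <- rev(x)
  y <- as.numeric(signal::filter(signal::Ma(b), x))
  if (reverse) rev(y) else y
}

#' Resample a record or signal to a target rate
#'
#' Rational-ratio resampling with zero-phase FIR anti-alias filtering: the
#' signal is zero-stuffed by the rational numerator, lowpass filtered at 80%
#' of the smaller Nyquist frequency, then decimated. Output length is
#' `round(n * fs_target / fs)`.
#'
#' @param rec an [scg_record()] (all channels resampled) or numeric vector.
#' @param fs_target target rate in Hz.
#' @param fs source rate (only when `rec` is a bare vector).
#' @return same type as `rec`, at `fs_target`.
#' @export
resample_record <- function(rec, fs_target, fs = NULL) {
  assert_scalar_number(fs_target, "fs_target", min = .Machine$double.eps)
  if (inherits(rec, "scg_record")) {
    if (fs_target == rec$fs) return(rec)
    out <- lapply(rec$samples, resample_signal, fs = rec$fs, fs_target = fs_target)
    return(scg_record(out, fs = fs_target, subject_id = rec$subject_id))
  }
  if (is.null(fs)) abort("`fs` required for vector input", class = "scgkit_argument_error")
  resample_signal(rec, fs, fs_target)
}

resample_signal <- function(x, fs, fs_target) {
  if (fs_target == fs) return(x)
  r <- rational_ratio(fs_target / fs)
  p <- r[1]; q <- r[2]
  n_out <- round(length(x) * fs_target / fs)
  # zero-stuff by p, anti-alias at 80% of min(Nyquist_in, Nyquist_out), pick every q-th
  if (p > 1L) {
    up <- numeric(length(x) * p)
    up[seq(1L, length(up), by = p)] <- x * p
  } else {
    up <- x
  }
  fs_up <- fs * p
  cutoff <- 0.75 * min(fs, fs_target) / 2
  ntaps <- min(1601L, 2L * (17L * ceiling(fs_up / cutoff)) + 1L)
  if (length(up) <= 3L * ntaps) {
    abort("signal too short to resample with anti-alias filtering",
          class = "scgkit_length_error")
  }
  # Blackman window: its tiny passband ripple survives the forward-backward
  # squaring, keeping in-band tones amplitude-accurate to < 0.1%
  b <- signal::fir1(ntaps - 1L, cutoff / (fs_up / 2), type = "low",
                    window = signal::blackman(ntaps))
  npad <- 3L * ntaps
  n_up <- length(up)
  left <- 2 * up[1] - up[(npad + 1L):2L]
  right <- 2 * up[n_up] - up[(n_up - 1L):(n_up - npad)]
  yp <- fir_causal(fir_causal(c(left, up, right), b), b, reverse = TRUE)
  y <- yp[(npad + 1L):(npad + n_up)]
  idx <- 1L + (seq_len(n_out) - 1L) * q
  idx[idx > length(y)] <- length(y)
  y[idx]
}

# Continued-fraction rational approximation of a positive ratio.
rational_ratio <- function(r, max_den = 1000L) {
  a <- r
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  repeat {
    ai <- floor(a)
    p2 <- ai * p1 + p0; q2 <- ai * q1 + q0
    if (q2 > max_den || abs(p2 / q2 - r) < 1e-12) {
      if (q2 > max_den) break
      p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
      break
    }
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    frac <- a - ai
    if (frac < 1e-12) break
    a <- 1 / frac
  }
  c(as.integer(p1), as.integer(q1))
}

#' Z-score a signal
#'
#' Whole-record normalization to zero mean and unit standard deviation
#' (population convention), the scale-invariance step applied before beat
#' detection. The original mean and standard deviation are retained.
#'
#' @param x numeric samples.
#' @param fs optional sampling rate, carried along for convenience.
#' @return a `preprocessed_signal` list with `xz`, `mu`, `sigma`, `fs`.
#' @export
zscore <- function(x, fs = NULL) {
  x <- as.numeric(x)
  if (length(x) < 2L) abort("need >= 2 samples", class = "scgkit_length_error")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (!is.finite(sigma) || sigma <= 0) {
    abort("constant (zero-variance) signal cannot be z-scored",
          class = "scgkit_degenerate_signal_error")
  }
  structure(list(xz = (x - mu) / sigma, mu = mu, sigma = sigma, fs = fs),
            class = "preprocessed_signal")
}

#' Standard preprocessing for one channel
#'
#' Resamples to `fs_target`, applies the zero-phase bandpass, and z-scores:
#' the default band is the SCG band (1-20 Hz); use 0.5-30 Hz for ECG.
#'
#' @param x numeric samples.
#' @param fs native sampling rate (Hz).
#' @param fs_target analysis rate (Hz), default 500.
#' @param band passband edges in Hz, default `c(1, 20)`.
#' @param numtaps FIR length, default 513.
#' @return a `preprocessed_signal` (`fs` = `fs_target`).
#' @export
preprocess_channel <- function(x, fs, fs_target = 500, band = c(1, 20),
                               numtaps = 513L) {
  if (fs != fs_target) {
    x <- resample_signal(x, fs, fs_target)
  }
  x <- bandpass_zero_phase(x, fs_target, filter_spec(band[1], band[2], numtaps))
  zscore(x, fs = fs_target)
}
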