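# Minimal WFDB (PhysioNet) record support: single-segment records, one shared
# .dat file, format 16 (interleaved little-endian int16) — the layout used by
# typical multichannel physiological benchmark recordings.

read_wfdb <- function(path, subject_id = NULL) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) {
    abort(sprintf("WFDB header not found: %s", hea), class = "scgkit_io_error")
  }
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(top) < 4L) {
    abort("malformed WFDB header line", class = "scgkit_format_error")
  }
  nsig <- as.integer(top[[2]])
  fs <- as.numeric(sub("/.*$", "", top[[3]]))  # strip counter-frequency suffix
  nsamp <- as.numeric(top[[4]])
  sig_lines <- lines[seq(2L, 1L + nsig)]
  sig <- lapply(sig_lines, parse_wfdb_signal_line)
  dat_files <- vapply(sig, `[[`, "", "file")
  if (length(unique(dat_files)) != 1L) {
    abort("multi-.dat WFDB records are not supported", class = "scgkit_format_error")
  }
  if (any(vapply(sig, `[[`, 0, "format") != 16)) {
    abort("only WFDB format 16 is supported", class = "scgkit_format_error")
  }
  dat <- file.path(dirname(hea), dat_files[[1]])
  if (!file.exists(dat)) {
    abort(sprintf("WFDB data file not found: %s", dat), class = "scgkit_io_error")
  }
  raw <- readBin(dat, what = "integer", size = 2L, signed = TRUE,
                 endian = "little", n = nsig * nsamp)
  if (length(raw) %% nsig != 0L) {
    abort("WFDB data length is not a multiple of the channel count",
          class = "scgkit_format_error")
  }
  mat <- matrix(raw, nrow = nsig)
  samples <- lapply(seq_len(nsig), function(i) {
    (mat[i, ] - sig[[i]]$baseline) / sig[[i]]$gain
  })
  names(samples) <- vapply(sig, `[[`, "", "desc")
  scg_record(samples, fs = fs,
             subject_id = subject_id %||% basename(base))
}

parse_wfdb_signal_line <- function(line) {
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  gain_tok <- if (length(tok) >= 3L) tok[[3]] else "200"
  units <- sub("^[^/]*/?", "", gain_tok)
  gb <- sub("/.*$", "", gain_tok)
  baseline <- 0
  if (grepl("\\(", gb)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", gb))
    gb <- sub("\\(.*$", "", gb)
  }
  gain <- as.numeric(gb)
  if (!is.finite(gain) || gain == 0) gain <- 200
  desc <- if (length(tok) >= 9L) paste(tok[9:length(tok)], collapse = " ") else ""
  list(file = tok[[1]], format = as.numeric(sub("x.*$", "", tok[[2]])),
       gain = gain, baseline = baseline,
       units = if (nzchar(units)) units else "mV", desc = desc)
}

write_wfdb <- function(rec, path) {
  base <- sub("\\.hea$", "", path)
  name <- basename(base)
  nsig <- length(rec$samples)
  gains <- vapply(rec$samples, function(x) {
    m <- max(abs(x))
    if (m == 0) 1 else 30000 / m
  }, numeric(1))
  mat <- matrix(0L, nrow = nsig, ncol = rec$n)
  for (i in seq_len(nsig)) {
    mat[i, ] <- as.integer(pmin(pmax(round(rec$samples[[i]] * gains[[i]]),
                                     -32768), 32767))
  }
  writeBin(as.integer(mat), paste0(base, ".dat"), size = 2L, endian = "little")
  sig_lines <- vapply(seq_len(nsig), function(i) {
    sprintf("%s.dat 16 %.6f(0)/au 16 0 %d 0 0 %s",
            name, gains[[i]], mat[i, 1], rec$channel_names[[i]])
  }, character(1))
  writeLines(c(sprintf("%s %d %g %d", name, nsig, rec$fs, rec$n), sig_lines),
             paste0(base, ".hea"))
  invisible(base)
}
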