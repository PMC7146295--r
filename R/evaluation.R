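#' Pan-Tompkins R-peak detection
#'
#' Classic QRS chain for the ECG reference: 5-15 Hz bandpass, five-point
#' derivative, squaring, 150 ms moving-window integration, adaptive
#' signal/noise thresholds with a 200 ms refractory period and RR-based
#' search-back. Used only to benchmark the SCG detector.
#'
#' @param ecg ECG samples (filtered or raw).
#' @param fs sampling rate in Hz (>= 200).
#' @return tibble of class `scg_rpeaks` with columns `peak`, `time_s`.
#' @export
pan_tompkins_rpeaks <- function(ecg, fs) {
  if (fs < 200) abort("Pan-Tompkins needs fs >= 200 Hz", class = "scgkit_argument_error")
  if (sd(ecg) == 0) return(new_rpeaks(numeric(0), fs))
  ntaps <- 101L
  bp <- bandpass_zero_phase(ecg, fs, filter_spec(5, 15, ntaps))
  der <- fir_causal(bp, c(1, 2, 0, -2, -1) * fs / 8)
  der <- c(der[-(1:2)], 0, 0)                       # recenter the 5-tap stencil
  sq <- der^2
  w <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  mwi[is.na(mwi)] <- 0
  refr <- round(0.2 * fs)
  # local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (length(cand) == 0L) return(new_rpeaks(numeric(0), fs))
  spki <- max(mwi[seq_len(min(length(mwi), 2L * fs))]) * 0.5
  npki <- mean(mwi[seq_len(min(length(mwi), 2L * fs))]) * 0.5
  thr <- npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  rr_avg <- NA_real_
  i <- 1L
  while (i <= length(cand)) {
    pk <- cand[i]
    if (length(peaks) && pk - peaks[length(peaks)] < refr) {
      if (mwi[pk] > mwi[peaks[length(peaks)]]) peaks[length(peaks)] <- pk
      i <- i + 1L
      next
    }
    if (mwi[pk] >= thr) {
      peaks <- c(peaks, pk)
      spki <- 0.125 * mwi[pk] + 0.875 * spki
      if (length(peaks) > 1L) {
        rr <- diff(tail(peaks, 9L))
        rr_avg <- mean(rr)
      }
    } else {
      npki <- 0.125 * mwi[pk] + 0.875 * npki
      # search-back: a long gap suggests a missed beat above half-threshold
      if (length(peaks) && !is.na(rr_avg) && pk - peaks[length(peaks)] > 1.66 * rr_avg) {
        seg <- cand[cand > peaks[length(peaks)] + refr & cand <= pk]
        seg <- seg[mwi[seg] >= thr / 2]
        if (length(seg)) {
          back <- seg[which.max(mwi[seg])]
          peaks <- c(peaks, back)
          spki <- 0.25 * mwi[back] + 0.75 * spki
          peaks <- sort(peaks)
        }
      }
    }
    thr <- npki + 0.25 * (spki - npki)
    i <- i + 1L
  }
  # refine each fiducial to the bandpassed-ECG maximum just before the MWI peak
  half <- round(0.10 * fs)
  ref <- vapply(peaks, function(pk) {
    a <- max(1L, pk - 2L * half)
    as.integer(a + which.max(abs(bp[a:min(length(bp), pk)])) - 1L)
  }, integer(1))
  new_rpeaks((sort(unique(ref)) - 1) / fs, fs)
}

new_rpeaks <- function(times_s, fs) {
  out <- tibble(peak = seq_along(times_s), time_s = times_s)
  class(out) <- c("scg_rpeaks", class(out))
  attr(out, "fs") <- fs
  out
}

#' Match SCG annotations against ECG reference beats
#'
#' Tolerance-window protocol: the expected SCG location of each R peak is the
#' R time plus a per-subject delay (median over the first `n_delay` annotated
#' beats of the lag from the preceding R peak). A beat inside the
#' `tolerance_ms` window centered there is a true positive; an empty window
#' is a false negative; an unmatched beat between the first and last window
#' is a false positive (one each); an inter-window gap without any beat is a
#' true negative. Consecutive true-positive windows yield matched
#' (tRR, tCC) interval pairs.
#'
#' @param ref R-peak times: an `scg_rpeaks` tibble or numeric seconds.
#' @param ann SCG annotations: an `scg_annotations` tibble or numeric seconds.
#' @param tolerance_ms total tolerance window length (default 100 ms).
#' @param delay_ms optional fixed R-to-SCG delay; estimated when `NULL`.
#' @param n_delay beats used for delay estimation (default 20).
#' @return a `match_result`: counts `tp`, `fp`, `fn`, `tn`, tibble `pairs`
#'   (`t_rr_ms`, `t_cc_ms`), `delay_ms`, `tolerance_ms`.
#' @export
match_beats <- function(ref, ann, tolerance_ms = 100, delay_ms = NULL,
                        n_delay = 20L) {
  r <- if (is.data.frame(ref)) ref$time_s else as.numeric(ref)
  a <- if (is.data.frame(ann)) ann$time_s else as.numeric(ann)
  if (length(r) < 2L || length(a) < 1L) {
    abort("need >= 2 reference beats and >= 1 annotation",
          class = "scgkit_argument_error")
  }
  if (any(diff(r) * 1000 < tolerance_ms)) {
    abort("reference intervals shorter than the tolerance window (overlap)",
          class = "scgkit_protocol_error")
  }
  if (is.null(delay_ms)) {
    # signed offset of each annotated beat from its nearest R peak
    lag_s <- vapply(head(a, n_delay), function(t) t - r[which.min(abs(r - t))],
                    numeric(1))
    delay_ms <- median(lag_s) * 1000
  }
  centers <- r + delay_ms / 1000
  half <- tolerance_ms / 2000
  matched_ann <- rep(NA_integer_, length(centers))
  used <- logical(length(a))
  for (i in seq_along(centers)) {
    inside <- which(!used & abs(a - centers[i]) <= half)
    if (length(inside)) {
      j <- inside[which.min(abs(a[inside] - centers[i]))]
      matched_ann[i] <- j
      used[j] <- TRUE
    }
  }
  tp <- sum(!is.na(matched_ann))
  fn <- sum(is.na(matched_ann))
  span_ok <- a >= centers[1] - half & a <= centers[length(centers)] + half
  fp <- sum(!used & span_ok)
  gaps_lo <- centers[-length(centers)] + half
  gaps_hi <- centers[-1] - half
  tn <- sum(vapply(seq_along(gaps_lo), function(g) {
    !any(a > gaps_lo[g] & a < gaps_hi[g])
  }, logical(1)))
  ok <- which(!is.na(matched_ann))
  consec <- ok[c(FALSE, diff(ok) == 1L)]
  pairs <- tibble(
    t_rr_ms = (r[consec] - r[consec - 1L]) * 1000,
    t_cc_ms = (a[matched_ann[consec]] - a[matched_ann[consec - 1L]]) * 1000
  )
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, pairs = pairs,
                 delay_ms = delay_ms, tolerance_ms = tolerance_ms),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP=%d FP=%d FN=%d TN=%d (delay %.1f ms)\n",
              x$tp, x$fp, x$fn, x$tn, x$delay_ms))
  invisible(x)
}

#' Detection scores from a match result
#'
#' Sensitivity TP/(TP+FN), precision TP/(TP+FP), specificity TN/(TN+FP),
#' as fractions in [0, 1]. Zero denominators yield NaN with a warning.
#'
#' @param m a [match_beats()] result.
#' @return tibble with `sensitivity`, `precision`, `specificity`.
#' @export
detection_metrics <- function(m) {
  stopifnot(inherits(m, "match_result"))
  ratio <- function(num, den, nm) {
    if (den == 0) {
      warn(sprintf("%s undefined (zero denominator)", nm))
      return(NaN)
    }
    num / den
  }
  tibble(sensitivity = ratio(m$tp, m$tp + m$fn, "sensitivity"),
         precision = ratio(m$tp, m$tp + m$fp, "precision"),
         specificity = ratio(m$tn, m$tn + m$fp, "specificity"))
}

#' Inter-beat interval error statistics
#'
#' For matched interval pairs, the errors `e_i = tRR_i - tCC_i` with their
#' mean, sample standard deviation, RMSE and the coefficient of determination
#' `R2 = 100 * (1 - sum(e^2) / sum((tRR - mean(tRR))^2))`.
#'
#' @param pairs tibble with `t_rr_ms`, `t_cc_ms` (e.g. from [match_beats()]),
#'   or a `match_result`.
#' @return an `interval_error_report`: `errors_ms`, `mu_e`, `sigma_e`,
#'   `rmse`, `r2_pct`, `n`.
#' @export
interval_errors <- function(pairs) {
  if (inherits(pairs, "match_result")) pairs <- pairs$pairs
  if (nrow(pairs) < 2L) {
    abort("need >= 2 matched interval pairs", class = "scgkit_insufficient_data_error")
  }
  e <- pairs$t_rr_ms - pairs$t_cc_ms
  ss_tot <- sum((pairs$t_rr_ms - mean(pairs$t_rr_ms))^2)
  r2 <- if (ss_tot == 0) {
    warn("constant reference intervals: R2 undefined")
    NA_real_
  } else {
    100 * (1 - sum(e^2) / ss_tot)
  }
  structure(list(errors_ms = e, mu_e = mean(e), sigma_e = sd(e),
                 rmse = sqrt(mean(e^2)), r2_pct = r2, n = length(e)),
            class = "interval_error_report")
}

#' @export
print.interval_error_report <- function(x, ...) {
  cat(sprintf("<interval_error_report> n=%d  mu_e=%.3f ms  sigma_e=%.3f ms  RMSE=%.3f ms  R2=%.2f%%\n",
              x$n, x$mu_e, x$sigma_e, x$rmse, x$r2_pct))
  invisible(x)
}

#' @rdname interval_errors
#' @param x an `interval_error_report`.
#' @param ... unused.
#' @export
glance.interval_error_report <- function(x, ...) {
  tibble(n = x$n, mu_e_ms = x$mu_e, sigma_e_ms = x$sigma_e, rmse_ms = x$rmse,
         r2_pct = x$r2_pct)
}

#' Bland-Altman agreement data
#'
#' Per matched pair: abscissa `(tRR + tCC) / 2`, ordinate `e = tRR - tCC`,
#' with the bias, limits of agreement (+/- 2 sample standard deviations) and
#' RMSE as attributes.
#'
#' @inheritParams interval_errors
#' @return tibble of class `bland_altman` with `mean_ms`, `error_ms`;
#'   attributes `mu_e`, `two_sigma`, `rmse`.
#' @export
bland_altman <- function(pairs) {
  if (inherits(pairs, "match_result")) pairs <- pairs$pairs
  if (nrow(pairs) < 2L) {
    abort("need >= 2 matched interval pairs", class = "scgkit_insufficient_data_error")
  }
  e <- pairs$t_rr_ms - pairs$t_cc_ms
  out <- tibble(mean_ms = (pairs$t_rr_ms + pairs$t_cc_ms) / 2, error_ms = e)
  class(out) <- c("bland_altman", class(out))
  attr(out, "mu_e") <- mean(e)
  attr(out, "two_sigma") <- 2 * sd(e)
  attr(out, "rmse") <- sqrt(mean(e^2))
  out
}

#' K-means clustering of latent codes
#'
#' Clusters the posterior means with multiple restarts and a fixed seed.
#'
#' @param codes a [encode_beats()] result (or numeric matrix).
#' @param n_clusters number of clusters (default: number of distinct subject
#'   ids carried by `codes`).
#' @param seed RNG seed (default 1).
#' @param nstart random restarts (default 10).
#' @return integer vector of hard labels.
#' @export
cluster_latent <- function(codes, n_clusters = NULL, seed = 1L, nstart = 10L) {
  mu <- if (inherits(codes, "latent_codes")) codes$mu else as.matrix(codes)
  if (is.null(n_clusters)) {
    sids <- if (inherits(codes, "latent_codes")) unique(codes$subject_ids) else NULL
    if (is.null(sids) || anyNA(sids)) {
      abort("n_clusters required when codes carry no subject ids",
            class = "scgkit_argument_error")
    }
    n_clusters <- length(sids)
  }
  if (n_clusters < 2L || nrow(mu) < n_clusters) {
    abort("need n_clusters >= 2 and at least that many rows",
          class = "scgkit_argument_error")
  }
  if (all(apply(mu, 2, function(col) diff(range(col)) == 0))) {
    warn("all latent codes identical: returning a single cluster")
    return(rep(1L, nrow(mu)))
  }
  with_local_seed(child_seed(seed, 3),
                  kmeans(mu, centers = n_clusters, nstart = nstart,
                         iter.max = 100L)$cluster)
}

# ---- clustering quality ---------------------------------------------------

#' Chance-adjusted and entropy-based clustering scores
#'
#' Adjusted Rand index, adjusted mutual information (arithmetic mean
#' normalization), completeness and homogeneity between a predicted labeling
#' and the ground truth. All are at most 1; a perfect labeling scores 1 in
#' each, and the two adjusted scores are near 0 for random labelings.
#'
#' @param pred predicted cluster labels.
#' @param truth ground-truth class labels (same length).
#' @return tibble with `adjusted_rand`, `adjusted_mutual_info`,
#'   `completeness`, `homogeneity`.
#' @export
cluster_scores <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  ct <- table(truth, pred)
  n <- sum(ct)
  ai <- rowSums(ct); bj <- colSums(ct)
  # adjusted Rand
  sum_nij <- sum(choose(ct, 2))
  sum_ai <- sum(choose(ai, 2)); sum_bj <- sum(choose(bj, 2))
  exp_idx <- sum_ai * sum_bj / choose(n, 2)
  max_idx <- (sum_ai + sum_bj) / 2
  ari <- if (max_idx == exp_idx) 1 else (sum_nij - exp_idx) / (max_idx - exp_idx)
  # entropies and mutual information (natural log)
  h <- function(cnt) {
    p <- cnt[cnt > 0] / n
    -sum(p * log(p))
  }
  hu <- h(ai); hv <- h(bj)
  nz <- which(ct > 0)
  pij <- ct[nz] / n
  mi <- sum(pij * log(pij * n^2 / (rep(ai, times = ncol(ct))[nz] *
                                     rep(bj, each = nrow(ct))[nz])))
  homogeneity <- if (hu == 0) 1 else 1 - cond_entropy(ct, bj, n) / hu
  completeness <- if (hv == 0) 1 else 1 - cond_entropy(t(ct), ai, n) / hv
  emi <- expected_mi(ai, bj, n)
  denom <- (hu + hv) / 2 - emi
  ami <- if (abs(denom) < 1e-12) {
    if (abs(mi - emi) < 1e-12) 1 else 0
  } else {
    (mi - emi) / denom
  }
  tibble(adjusted_rand = ari, adjusted_mutual_info = ami,
         completeness = completeness, homogeneity = homogeneity)
}

# H(rows | cols) of a contingency table
cond_entropy <- function(ct, colsums, n) {
  val <- 0
  for (j in seq_along(colsums)) {
    cnt <- ct[, j]
    cnt <- cnt[cnt > 0]
    if (length(cnt)) val <- val - sum(cnt / n * log(cnt / colsums[j]))
  }
  val
}

# Expected mutual information under the permutation (hypergeometric) model.
expected_mi <- function(ai, bj, n) {
  emi <- 0
  lgn <- lgamma(n + 1)
  for (a in ai) {
    for (b in bj) {
      lo <- max(1, a + b - n)
      hi <- min(a, b)
      if (hi < lo) next
      nij <- lo:hi
      term <- nij / n * log(n * nij / (a * b))
      lp <- lgamma(a + 1) + lgamma(b + 1) + lgamma(n - a + 1) + lgamma(n - b + 1) -
        lgn - lgamma(nij + 1) - lgamma(a - nij + 1) - lgamma(b - nij + 1) -
        lgamma(n - a - b + nij + 1)
      emi <- emi + sum(term * exp(lp))
    }
  }
  emi
}

#' Fit the architecture-effect linear model
#'
#' Ordinary least squares of a clustering performance score on the
#' architecture offsets from the baseline (Ld = 2, Nconv = 1):
#' `yperf = beta0 + beta1 * (sqrt(Ld) - sqrt(2)) + beta2 * (Nconv - 1)`.
#' The square-root covariate encodes the sub-linear benefit of enlarging the
#' latent space.
#'
#' @param design data frame with columns `ld`, `n_conv` and the response
#'   (named by `response`).
#' @param response response column name (default `"yperf"`).
#' @param baseline baseline `c(ld, n_conv)` (default `c(2, 1)`).
#' @return a `meta_model_fit`: `beta0`, `beta1`, `beta2`, `r2_pct`, `design`,
#'   and the underlying `lm` fit.
#' @export
fit_meta_model <- function(design, response = "yperf", baseline = c(2, 1)) {
  design <- as_tibble(design)
  if (!all(c("ld", "n_conv", response) %in% names(design))) {
    abort(sprintf("design needs columns ld, n_conv, %s", response),
          class = "scgkit_argument_error")
  }
  if (nrow(design) < 3L) {
    abort("need >= 3 design points", class = "scgkit_argument_error")
  }
  df <- tibble(y = design[[response]],
               d_ld = sqrt(design$ld) - sqrt(baseline[1]),
               d_nconv = design$n_conv - baseline[2])
  X <- cbind(1, df$d_ld, df$d_nconv)
  if (qr(X)$rank < 3L) {
    abort("collinear design: cannot separate the Ld and Nconv effects",
          class = "scgkit_rank_deficiency_error")
  }
  fit <- lm(y ~ d_ld + d_nconv, data = df)
  smry <- suppressWarnings(summary(fit))
  structure(list(beta0 = unname(coef(fit)[1]), beta1 = unname(coef(fit)[2]),
                 beta2 = unname(coef(fit)[3]),
                 r2_pct = 100 * smry$r.squared,
                 design = dplyr::bind_cols(design["ld"], design["n_conv"],
                                           df), fit = fit),
            class = "meta_model_fit")
}

#' @export
print.meta_model_fit <- function(x, ...) {
  cat(sprintf("<meta_model_fit> y = %.3f + %.3f * dLd + %.3f * dNconv  (R2 = %.1f%%)\n",
              x$beta0, x$beta1, x$beta2, x$r2_pct))
  invisible(x)
}

#' @rdname fit_meta_model
#' @param x a `meta_model_fit`.
#' @param ... unused.
#' @export
tidy.meta_model_fit <- function(x, ...) {
  tibble(term = c("intercept", "delta_ld", "delta_nconv"),
         estimate = c(x$beta0, x$beta1, x$beta2),
         std.error = suppressWarnings(summary(x$fit))$coefficients[, "Std. Error"])
}

#' @rdname fit_meta_model
#' @export
glance.meta_model_fit <- function(x, ...) {
  tibble(r2_pct = x$r2_pct, n = nrow(x$design),
         sigma = suppressWarnings(summary(x$fit))$sigma)
}

#' Detection F1 as a function of the threshold multiplier k
#'
#' Runs the full detector at each fixed `k` (adaptive halving disabled, so
#' each point reflects that k alone) and scores it against reference beats.
#' Detection or calibration failures score 0.
#'
#' @param rec an [scg_record()].
#' @param ref_times_s reference beat times in seconds (e.g. ground truth or
#'   R peaks shifted by the subject delay).
#' @param k_values numeric vector of k values.
#' @param cfg base [detection_config()].
#' @param tolerance_ms matching tolerance (default 100).
#' @return tibble of class `k_sweep`: `k`, `sensitivity`, `precision`, `f1`,
#'   `n_beats`.
#' @export
detection_f1_by_k <- function(rec, ref_times_s, k_values,
                              cfg = detection_config(), tolerance_ms = 100) {
  rows <- lapply(k_values, function(kv) {
    cfg_k <- cfg
    cfg_k$k <- kv
    cfg_k$allow_k_halving <- FALSE
    res <- tryCatch({
      det <- detect_and_annotate(rec, cfg_k)
      m <- match_beats(ref_times_s, det$annotations, tolerance_ms = tolerance_ms)
      dm <- suppressWarnings(detection_metrics(m))
      tibble(k = kv, sensitivity = dm$sensitivity, precision = dm$precision,
             f1 = 2 * dm$sensitivity * dm$precision /
               (dm$sensitivity + dm$precision),
             n_beats = nrow(det$annotations))
    }, scgkit_detection_failure = function(e) NULL,
       scgkit_calibration_failure = function(e) NULL,
       scgkit_insufficient_data_error = function(e) NULL)
    res %||% tibble(k = kv, sensitivity = 0, precision = 0, f1 = 0, n_beats = 0L)
  })
  out <- dplyr::bind_rows(rows)
  out$f1[!is.finite(out$f1)] <- 0
  class(out) <- c("k_sweep", class(out))
  out
}

#' Score beat detection over a synthetic cohort
#'
#' Runs [detect_and_annotate()] per record, matches against the cohort's
#' ground-truth R peaks, and returns per-subject and pooled scores.
#'
#' @param cohort list of `synthetic_record`s from [simulate_cohort()].
#' @param cfg a [detection_config()].
#' @param tolerance_ms matching tolerance (default 100).
#' @return list: `per_subject` tibble (scores per record), `pooled_intervals`
#'   (an [interval_errors()] report over all matched pairs), `matches`.
#' @export
evaluate_cohort_detection <- function(cohort, cfg = detection_config(),
                                      tolerance_ms = 100) {
  per <- list(); matches <- list()
  for (sr in cohort) {
    det <- detect_and_annotate(sr$record, cfg)
    m <- match_beats(sr$truth_rpeaks_s, det$annotations,
                     tolerance_ms = tolerance_ms)
    dm <- detection_metrics(m)
    ie <- interval_errors(m)
    per[[sr$subject_id]] <- dplyr::bind_cols(
      tibble(subject_id = sr$subject_id, n_ref = length(sr$truth_rpeaks_s),
             n_det = nrow(det$annotations)),
      dm, glance(ie))
    matches[[sr$subject_id]] <- m
  }
  all_pairs <- dplyr::bind_rows(lapply(matches, `[[`, "pairs"))
  list(per_subject = dplyr::bind_rows(per),
       pooled_intervals = interval_errors(all_pairs),
       matches = matches)
}

#' Sweep VAE architectures and score latent clustering
#'
#' Trains one VAE per (Ld, Nconv) grid point on the same heartbeat matrix,
#' encodes the held-out test rows, clusters them with k-means (k = number of
#' subjects), and scores the clustering against the subject labels.
#'
#' @param beats a [heartbeat_matrix()].
#' @param grid data frame with columns `ld`, `n_conv` (default the 5 x 3 grid
#'   Ld in 2,4,8,16,32 by Nconv in 1,2,3).
#' @param seed seed shared by training, encoding and clustering.
#' @param epochs maximum epochs per fit.
#' @param minibatch mini-batch size (default 32).
#' @return tibble of class `arch_sweep`: grid columns plus the four
#'   clustering scores and the validation loss.
#' @export
architecture_sweep <- function(beats,
                               grid = expand.grid(ld = c(2, 4, 8, 16, 32),
                                                  n_conv = 1:3),
                               seed = 1L, epochs = 60L, minibatch = 32L) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- vae_config(n_conv = grid$n_conv[i], latent_dim = grid$ld[i],
                      minibatch = minibatch, epochs = epochs, seed = seed)
    model <- train_vae(build_vae(cfg), beats)
    test <- model$split$test
    codes <- encode_beats(model, beats$segments[test, , drop = FALSE],
                          subject_ids = beats$subject_ids[test])
    labels <- cluster_latent(codes, seed = seed)
    sc <- cluster_scores(labels, codes$subject_ids)
    dplyr::bind_cols(tibble(ld = grid$ld[i], n_conv = grid$n_conv[i]), sc,
                     tibble(val_loss = min(model$loss_report$val_total)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("arch_sweep", class(out))
  out
}
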