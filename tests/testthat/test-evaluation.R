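test_that("Pan-Tompkins finds spike-train R peaks and handles degenerate input", {
  fs <- 500
  n <- 20L * fs
  t <- (seq_len(n) - 1) / fs
  peaks_s <- seq(1, 19, by = 1)
  ecg <- rowSums(vapply(peaks_s, function(r) exp(-0.5 * ((t - r) / 0.008)^2),
                        numeric(n)))
  set.seed(3)
  ecg <- ecg + 0.01 * rnorm(n)
  rp <- pan_tompkins_rpeaks(ecg, fs)
  expect_equal(nrow(rp), length(peaks_s))
  expect_lt(max(vapply(rp$time_s, function(x) min(abs(x - peaks_s)), numeric(1))),
            0.02)
  # flatline -> no peaks
  expect_equal(nrow(pan_tompkins_rpeaks(rep(1, 5000), fs)), 0L)
  # amplitude scaling does not move the peaks (adaptive thresholds)
  rp2 <- pan_tompkins_rpeaks(ecg * 41, fs)
  expect_identical(rp$time_s, rp2$time_s)
  expect_error(pan_tompkins_rpeaks(ecg, 100), class = "scgkit_argument_error")
})

test_that("tolerance-window matching counts TP/FP/FN/TN as defined", {
  r <- seq(1, 30, by = 0.8)
  delay <- 0.12
  a <- r + delay
  m <- match_beats(r, a, tolerance_ms = 100)
  expect_equal(m$tp, length(r))
  expect_equal(m$fp, 0L)
  expect_equal(m$fn, 0L)
  expect_equal(m$tn, length(r) - 1L)
  expect_equal(m$delay_ms, 120, tolerance = 1e-6)
  # TP + FN equals the number of reference windows
  expect_equal(m$tp + m$fn, length(r))
  # deleting one annotation converts a TP into an FN
  m2 <- match_beats(r, a[-10], tolerance_ms = 100)
  expect_equal(m2$tp, length(r) - 1L)
  expect_equal(m2$fn, 1L)
  # one spurious mid-diastole annotation is exactly one FP and kills one TN
  m3 <- match_beats(r, sort(c(a, a[10] + 0.4)), tolerance_ms = 100)
  expect_equal(m3$fp, 1L)
  expect_equal(m3$tp, length(r))
  expect_equal(m3$tn, length(r) - 2L)
  # overlapping windows are a protocol violation
  expect_error(match_beats(c(1, 1.05), c(1.1, 1.16), tolerance_ms = 100),
               class = "scgkit_protocol_error")
})

test_that("detection scores are the three ratios with NaN on empty denominators", {
  m <- structure(list(tp = 99, fp = 1, fn = 1, tn = 99), class = "match_result")
  dm <- detection_metrics(m)
  expect_equal(dm$sensitivity, 0.99)
  expect_equal(dm$precision, 0.99)
  expect_equal(dm$specificity, 0.99)
  m0 <- structure(list(tp = 0, fp = 0, fn = 5, tn = 3), class = "match_result")
  expect_warning(dm0 <- detection_metrics(m0), "precision")
  expect_true(is.nan(dm0$precision))
  expect_equal(dm0$sensitivity, 0)
})

test_that("interval error statistics match their definitions", {
  p0 <- tibble::tibble(t_rr_ms = c(800, 900, 850), t_cc_ms = c(800, 900, 850))
  ie0 <- interval_errors(p0)
  expect_equal(ie0$mu_e, 0)
  expect_equal(ie0$sigma_e, 0)
  expect_equal(ie0$rmse, 0)
  expect_equal(ie0$r2_pct, 100)
  # hand case e = {3, -3}
  p1 <- tibble::tibble(t_rr_ms = c(803, 897), t_cc_ms = c(800, 900))
  ie1 <- interval_errors(p1)
  expect_equal(ie1$mu_e, 0)
  expect_equal(ie1$rmse, 3)
  expect_equal(ie1$sigma_e, 3 * sqrt(2))
  # identity RMSE^2 = mu^2 + sigma^2 (n-1)/n on random error vectors
  set.seed(8)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    trr <- runif(n, 700, 1000)
    e <- rnorm(n, 0, 5)
    ie <- interval_errors(tibble::tibble(t_rr_ms = trr, t_cc_ms = trr - e))
    expect_equal(ie$rmse^2, ie$mu_e^2 + ie$sigma_e^2 * (n - 1) / n,
                 tolerance = 1e-9)
  }
  expect_warning(interval_errors(tibble::tibble(t_rr_ms = c(800, 800),
                                                t_cc_ms = c(799, 801))),
                 "constant")
})

test_that("Bland-Altman pairs and limits follow their definitions", {
  p <- tibble::tibble(t_rr_ms = c(800, 900), t_cc_ms = c(802, 898))
  ba <- bland_altman(p)
  expect_equal(ba$mean_ms, c(801, 899))
  expect_equal(ba$error_ms, c(-2, 2))
  expect_equal(attr(ba, "two_sigma"), 2 * sd(c(-2, 2)))
  ba0 <- bland_altman(tibble::tibble(t_rr_ms = c(800, 900), t_cc_ms = c(800, 900)))
  expect_true(all(ba0$error_ms == 0))
})

test_that("k-means on latent codes separates blobs deterministically", {
  set.seed(6)
  mu <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 8), 50))
  lbl <- cluster_latent(mu, n_clusters = 2, seed = 4)
  expect_equal(length(unique(lbl[1:50])), 1L)
  expect_equal(length(unique(lbl[51:100])), 1L)
  expect_false(lbl[1] == lbl[51])
  expect_identical(lbl, cluster_latent(mu, n_clusters = 2, seed = 4))
  expect_warning(cluster_latent(matrix(1, 10, 2), n_clusters = 2), "identical")
})

test_that("clustering scores agree with an independent implementation", {
  # fixture scored with scikit-learn 1.9.0 (adjusted_rand_score,
  # adjusted_mutual_info_score, homogeneity_score, completeness_score)
  truth <- c(3, 2, 2, 3, 2, 3, 3, 0, 0, 1, 1, 3, 3, 0, 1, 3, 0, 3, 0, 1, 3, 1,
             1, 1, 2, 1, 3, 1, 1, 2, 2, 2, 2, 3, 3, 3, 2, 2, 1, 3, 1, 0, 3, 0,
             3, 2, 0, 0, 1, 0, 0, 2, 3, 1, 3, 3, 3, 2, 1, 2)
  pred <- c(2, 2, 2, 3, 2, 3, 3, 0, 0, 1, 2, 3, 2, 2, 1, 3, 0, 3, 0, 3, 3, 1,
            1, 1, 0, 1, 3, 1, 1, 2, 2, 2, 2, 3, 3, 3, 2, 2, 1, 3, 0, 0, 3, 0,
            3, 2, 0, 0, 1, 0, 0, 2, 0, 1, 3, 0, 3, 2, 1, 3)
  sc <- cluster_scores(pred, truth)
  expect_equal(sc$adjusted_rand, 0.5843033009007149, tolerance = 1e-12)
  expect_equal(sc$adjusted_mutual_info, 0.5632275599022598, tolerance = 1e-9)
  expect_equal(sc$homogeneity, 0.5922309005737539, tolerance = 1e-12)
  expect_equal(sc$completeness, 0.5871686064340041, tolerance = 1e-12)
})

test_that("clustering scores have the right fixed points and invariances", {
  x <- rep(1:4, each = 10)
  perfect <- cluster_scores(x, x)
  expect_true(all(abs(unlist(perfect) - 1) < 1e-12))
  # label permutation of the prediction changes nothing
  y <- c(5, 3, 1, 2)[x]
  perm <- cluster_scores(y, x)
  expect_equal(unlist(perm), unlist(perfect), tolerance = 1e-12)
  # random labeling is chance-corrected to ~0
  set.seed(13)
  n <- 10000
  truth <- sample(20, n, replace = TRUE)
  pred <- sample(20, n, replace = TRUE)
  sc <- cluster_scores(pred, truth)
  expect_lt(abs(sc$adjusted_rand), 0.02)
  # cross-check the adjusted Rand against mclust
  skip_if_not_installed("mclust")
  set.seed(14)
  for (i in 1:5) {
    a <- sample(4, 80, replace = TRUE)
    b <- sample(3, 80, replace = TRUE)
    expect_equal(cluster_scores(b, a)$adjusted_rand,
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("the architecture linear model recovers noiseless coefficients exactly", {
  grid <- expand.grid(ld = c(2, 4, 8, 16, 32), n_conv = 1:3)
  grid$yperf <- 0.5 + 0.1 * (sqrt(grid$ld) - sqrt(2)) + 0.02 * (grid$n_conv - 1)
  fit <- fit_meta_model(grid)
  expect_equal(fit$beta0, 0.5, tolerance = 1e-10)
  expect_equal(fit$beta1, 0.1, tolerance = 1e-10)
  expect_equal(fit$beta2, 0.02, tolerance = 1e-10)
  expect_equal(fit$r2_pct, 100, tolerance = 1e-10)
  # OLS equals the normal-equations oracle
  set.seed(21)
  grid$yperf <- grid$yperf + rnorm(nrow(grid), 0, 0.05)
  fit2 <- fit_meta_model(grid)
  X <- cbind(1, sqrt(grid$ld) - sqrt(2), grid$n_conv - 1)
  beta <- solve(t(X) %*% X, t(X) %*% grid$yperf)
  expect_equal(c(fit2$beta0, fit2$beta1, fit2$beta2), as.numeric(beta),
               tolerance = 1e-9)
  # collinear designs are refused
  bad <- data.frame(ld = c(2, 2, 2), n_conv = c(1, 1, 1), yperf = 1:3)
  expect_error(fit_meta_model(bad), class = "scgkit_rank_deficiency_error")
  expect_error(fit_meta_model(grid[1:2, ]), class = "scgkit_argument_error")
})

test_that("cohort evaluation ties the pipeline together", {
  coh <- noisy_cohort_small()
  ev <- evaluate_cohort_detection(coh)
  expect_equal(nrow(ev$per_subject), length(coh))
  expect_true(all(ev$per_subject$sensitivity >= 0.95))
  expect_true(all(ev$per_subject$precision >= 0.95))
  expect_lt(ev$pooled_intervals$rmse, 3)
  expect_gt(ev$pooled_intervals$r2_pct, 95)
})
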