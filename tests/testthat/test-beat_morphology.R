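test_that("beat segmentation applies the crop, decimation, saturation and offset", {
  fs <- 500
  n <- 3000
  ann <- c(500L, 1500L)
  # flat signal around a beat -> constant 5 after the offset
  seg0 <- segment_heartbeats(numeric(n), fs, ann, "A")
  expect_equal(dim(seg0$segments), c(2L, 200L))
  expect_true(all(seg0$segments == 5))
  # extreme sample saturates at +/-5 before the offset
  x <- numeric(n)
  x[500] <- 7          # at the anchor, kept by the decimation grid
  x[1500] <- -9
  seg1 <- segment_heartbeats(x, fs, ann, "A")
  expect_equal(max(seg1$segments[1, ]), 10)
  expect_equal(min(seg1$segments[2, ]), 0)
  expect_true(all(seg1$segments >= 0 & seg1$segments <= 10))
  # a beat 50 ms from the start underflows its window and is dropped
  seg2 <- segment_heartbeats(numeric(n), fs, c(25L, 1500L), "A")
  expect_equal(nrow(seg2$segments), 1L)
  # no complete windows -> empty matrix, not an error
  seg3 <- segment_heartbeats(numeric(400), fs, 10L, "A")
  expect_equal(nrow(seg3$segments), 0L)
  # only an 800 ms / 400 sample window is supported
  expect_error(segment_heartbeats(numeric(n), 250, ann),
               class = "scgkit_argument_error")
})

test_that("heartbeat matrices validate, combine and round-trip as TSV", {
  m1 <- heartbeat_matrix(matrix(5, 3, 200), rep("A", 3), 1:3)
  m2 <- heartbeat_matrix(matrix(4, 2, 200), rep("B", 2), 4:5)
  both <- bind_heartbeats(m1, m2)
  expect_equal(nrow(both$segments), 5L)
  expect_equal(both$subject_ids, c("A", "A", "A", "B", "B"))
  expect_error(heartbeat_matrix(matrix(1, 2, 100), c("A", "B")),
               class = "scgkit_shape_error")
  expect_error(heartbeat_matrix(matrix(12, 1, 200), "A"),
               class = "scgkit_format_error")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_heartbeats(both, path)
  back <- read_heartbeats(path)
  expect_equal(back$segments, both$segments, ignore_attr = TRUE)
  expect_equal(back$subject_ids, both$subject_ids)
})

test_that("the Gaussian KL divergence matches its closed form", {
  expect_equal(kl_gaussian(0, 0), 0)
  expect_equal(kl_gaussian(1, 0), 0.5)
  expect_equal(kl_gaussian(c(1, 1), c(0, 0)), 1)
  # hand-derived: mu=2, log_var=log(4) -> 0.5*(4 + 4 - 1 - log 4)
  expect_equal(kl_gaussian(2, log(4)), 0.5 * (4 + 4 - 1 - log(4)))
  set.seed(11)
  for (i in 1:1000) {
    expect_gte(kl_gaussian(rnorm(4), rnorm(4)), 0)
  }
})

test_that("VAE construction enforces the pooling arithmetic", {
  expect_equal(build_vae(vae_config(n_conv = 2))$arch$L_end, 50L)   # 200->100->50
  expect_equal(build_vae(vae_config(n_conv = 3, latent_dim = 8))$arch$L_end, 25L)
  expect_error(vae_config(n_conv = 4), class = "scgkit_config_error")
  expect_error(vae_config(kernel_size = 4), class = "scgkit_config_error")
})

test_that("decoder output length is 200 for every valid depth (anti-symmetry)", {
  X <- matrix(runif(4 * 200, 0, 10), 4)
  for (nc in 1:3) {
    m <- build_vae(vae_config(n_conv = nc, latent_dim = 4, filters_base = 4,
                              seed = nc))
    fw <- scgkit:::vae_forward(m$params, m$arch, X)
    expect_equal(dim(fw$Xhat), c(4L, 200L))
    expect_equal(ncol(fw$mu), 4L)
  }
})

test_that("loss components satisfy total = recon + kl and batch-permutation invariance", {
  set.seed(5)
  m <- build_vae(vae_config(n_conv = 2, latent_dim = 4, filters_base = 8, seed = 2))
  X <- matrix(runif(16 * 200, 0, 10), 16)
  ls <- vae_losses(m, X)
  expect_equal(ls$total, ls$recon + ls$kl, tolerance = 1e-6)
  expect_gte(ls$kl, 0)
  perm <- sample(16)
  lp <- vae_losses(m, X[perm, ])
  expect_equal(lp$kl, ls$kl, tolerance = 1e-9)
  expect_equal(lp$recon, ls$recon, tolerance = 1e-9)
})

test_that("analytic gradients match finite differences", {
  set.seed(9)
  cfg <- vae_config(n_conv = 2, latent_dim = 3, filters_base = 4, seed = 3)
  m <- build_vae(cfg)
  X <- matrix(runif(4 * 200, 0, 10), 4)
  eps <- matrix(rnorm(4 * 3), 4)
  fw <- scgkit:::vae_forward(m$params, m$arch, X, eps)
  g <- scgkit:::vae_backward(m$params, m$arch, X, fw)
  loss_at <- function(p) {
    f <- scgkit:::vae_forward(p, m$arch, X, eps)
    scgkit:::vae_losses_from_forward(f, X)$total
  }
  h <- 1e-6
  for (nm in c("enc1_W1", "enc2_W2", "fc_mu_W", "fc_lv_b", "dec_fc_W",
               "dec1_W1", "dec2_W2", "dec2_b2")) {
    idx <- which(g[[nm]] != 0)
    i <- if (length(idx)) idx[ceiling(length(idx) / 2)] else 1L
    p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + h
    p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - h
    num <- (loss_at(p1) - loss_at(p2)) / (2 * h)
    expect_equal(g[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("the split is stratified by subject and keeps the test set untouched", {
  segs <- matrix(runif(200 * 200, 0, 10), 200)
  beats <- heartbeat_matrix(segs, rep(c("A", "B"), each = 100))
  sp <- split_heartbeats(beats, seed = 3)
  expect_length(c(sp$train, sp$val, sp$test), 200L)
  expect_false(any(duplicated(c(sp$train, sp$val, sp$test))))
  for (sid in c("A", "B")) {
    for (set in sp) expect_gt(sum(beats$subject_ids[set] == sid), 0)
  }
  expect_equal(length(sp$train), 140L)
})

test_that("training reduces the loss, is reproducible and learns a degenerate dataset", {
  one_beat <- pmin(pmax(test_wavelet(500)[seq(1, 400, 2)] * 2, -5), 5) + 5
  segs <- matrix(rep(one_beat, each = 360), 360)
  beats <- heartbeat_matrix(segs, rep(c("A", "B"), 180))
  cfg <- vae_config(n_conv = 2, latent_dim = 2, filters_base = 8, epochs = 30,
                    minibatch = 16, patience = 30, seed = 21)
  model <- train_vae(build_vae(cfg), beats)
  lr <- model$loss_report
  expect_lt(lr$train_total[nrow(lr)], lr$train_total[1])
  expect_lt(min(lr$val_recon) / 200, 0.05)   # per-sample MSE in scaled units
  # identical seed -> identical trajectory
  model2 <- train_vae(build_vae(cfg), beats)
  expect_identical(model$loss_report$train_total, model2$loss_report$train_total)
  # reconstruction of the repeated beat is tight
  rec <- reconstruct_beats(model, segs[1:4, , drop = FALSE])
  expect_lt(mean((rec - segs[1:4, ])^2), 0.05)
  # encoding is deterministic in mu and has the configured width
  codes <- encode_beats(model, beats)
  expect_equal(ncol(codes$mu), 2L)
  expect_equal(codes$mu[1, ], codes$mu[2, ], tolerance = 1e-12)
  expect_error(encode_beats(model, matrix(0, 2, 100)),
               class = "scgkit_shape_error")
  # too little data for the mini-batch contract
  small <- heartbeat_matrix(segs[1:40, ], rep("A", 40))
  expect_error(train_vae(build_vae(cfg), small),
               class = "scgkit_insufficient_data_error")
})

test_that("a near-constant input drives the posterior towards the prior", {
  set.seed(2)
  segs <- matrix(5 + rnorm(320 * 200, 0, 1e-4), 320)
  segs <- pmin(pmax(segs, 0), 10)
  beats <- heartbeat_matrix(segs, rep("A", 320))
  cfg <- vae_config(n_conv = 1, latent_dim = 2, filters_base = 4, epochs = 15,
                    minibatch = 16, patience = 15, seed = 5)
  model <- train_vae(build_vae(cfg), beats, fractions = c(0.8, 0.1, 0.1))
  codes <- encode_beats(model, beats)
  expect_lt(mean(abs(codes$mu)), 0.1)
})
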