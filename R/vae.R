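#' Convolutional VAE configuration
#'
#' Architecture and training controls for the modular 1D-convolutional
#' variational autoencoder. The encoder is `n_conv` cascaded Conv-Stacks
#' (two 1D convolutions + a length-halving max-pool each) followed by two
#' parallel dense heads of `latent_dim` units (posterior mean and
#' log-variance); the decoder mirrors the encoder with nearest-neighbor
#' upsampling in place of pooling and a linear 200-sample output.
#'
#' @param n_conv number of Conv-Stacks (200 must be divisible by `2^n_conv`).
#' @param latent_dim latent dimensionality Ld (>= 1).
#' @param minibatch training mini-batch size (default 32).
#' @param filters_base filters of the first stack (default 16, doubling per
#'   stack).
#' @param kernel_size convolution kernel length (odd, default 3).
#' @param epochs maximum training epochs (default 200).
#' @param learning_rate Adam step size (default 1e-3).
#' @param patience early-stopping patience on validation loss (default 10).
#' @param seed seed for initialization, shuffling and reparameterization.
#' @return a `vae_config` list.
#' @export
vae_config <- function(n_conv = 2L, latent_dim = 8L, minibatch = 32L,
                       filters_base = 16L, kernel_size = 3L, epochs = 200L,
                       learning_rate = 1e-3, patience = 10L, seed = 1L) {
  n_conv <- as.integer(n_conv)
  if (n_conv < 1L || 200L %% (2L^n_conv) != 0L) {
    abort(sprintf("200 samples cannot be halved %d times (200 / 2^n_conv must be an integer)",
                  n_conv), class = "scgkit_config_error")
  }
  if (latent_dim < 1L) abort("latent_dim must be >= 1", class = "scgkit_config_error")
  if (minibatch < 1L) abort("minibatch must be >= 1", class = "scgkit_config_error")
  if (kernel_size %% 2L != 1L) abort("kernel_size must be odd", class = "scgkit_config_error")
  structure(list(n_conv = n_conv, latent_dim = as.integer(latent_dim),
                 minibatch = as.integer(minibatch),
                 filters_base = as.integer(filters_base),
                 kernel_size = as.integer(kernel_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 patience = as.integer(patience), seed = seed),
            class = "vae_config")
}

# ---- tensor primitives (arrays of dim (batch, length, channels)) ----------

im2col1d <- function(A, K) {
  d <- dim(A); B <- d[1]; L <- d[2]; Cin <- d[3]
  h <- (K - 1L) %/% 2L
  out <- array(0, c(B, L, K * Cin))
  for (bi in seq_len(K)) {
    o <- bi - h - 1L
    lr <- max(1L, 1L - o):min(L, L - o)
    out[, lr, (bi - 1L) * Cin + seq_len(Cin)] <- A[, lr + o, , drop = FALSE]
  }
  out
}

conv1d_fw <- function(A, W, b) {
  d <- dim(A); B <- d[1]; L <- d[2]; Cin <- d[3]
  K <- nrow(W) %/% Cin
  Acol <- im2col1d(A, K)
  M <- Acol; dim(M) <- c(B * L, K * Cin)
  Z <- M %*% W
  Z <- sweep(Z, 2, b, "+")
  dim(Z) <- c(B, L, ncol(W))
  list(Z = Z, Acol = Acol, Cin = Cin, K = K)
}

conv1d_bw <- function(dZ, cache, W) {
  d <- dim(dZ); B <- d[1]; L <- d[2]; Cout <- d[3]
  K <- cache$K; Cin <- cache$Cin
  dZm <- dZ; dim(dZm) <- c(B * L, Cout)
  Am <- cache$Acol; dim(Am) <- c(B * L, K * Cin)
  dW <- crossprod(Am, dZm)
  db <- colSums(dZm)
  dAcol <- dZm %*% t(W)
  dim(dAcol) <- c(B, L, K * Cin)
  dA <- array(0, c(B, L, Cin))
  h <- (K - 1L) %/% 2L
  for (bi in seq_len(K)) {
    o <- bi - h - 1L
    lr <- max(1L, 1L - o):min(L, L - o)
    dA[, lr + o, ] <- dA[, lr + o, , drop = FALSE] +
      dAcol[, lr, (bi - 1L) * Cin + seq_len(Cin), drop = FALSE]
  }
  list(dA = dA, dW = dW, db = db)
}

maxpool2_fw <- function(A) {
  L <- dim(A)[2]
  A1 <- A[, seq(1L, L, 2L), , drop = FALSE]
  A2 <- A[, seq(2L, L, 2L), , drop = FALSE]
  mask <- A1 >= A2
  list(P = A1 * mask + A2 * !mask, mask = mask)
}

maxpool2_bw <- function(dP, mask) {
  d <- dim(dP)
  dA <- array(0, c(d[1], d[2] * 2L, d[3]))
  dA[, seq(1L, d[2] * 2L, 2L), ] <- dP * mask
  dA[, seq(2L, d[2] * 2L, 2L), ] <- dP * !mask
  dA
}

upsample2_fw <- function(A) {
  d <- dim(A)
  O <- array(0, c(d[1], d[2] * 2L, d[3]))
  O[, seq(1L, d[2] * 2L, 2L), ] <- A
  O[, seq(2L, d[2] * 2L, 2L), ] <- A
  O
}

upsample2_bw <- function(dO) {
  L2 <- dim(dO)[2]
  dO[, seq(1L, L2, 2L), , drop = FALSE] + dO[, seq(2L, L2, 2L), , drop = FALSE]
}

# ---- model ----------------------------------------------------------------

vae_arch <- function(cfg) {
  n <- cfg$n_conv
  ch <- cfg$filters_base * 2L^(seq_len(n) - 1L)   # output channels per stack
  cin <- c(1L, ch[-n])                            # input channels per stack
  L_end <- 200L %/% 2L^n
  list(n = n, K = cfg$kernel_size, ch = ch, cin = cin,
       L_end = L_end, C_end = ch[n], F = L_end * ch[n])
}

#' Build an untrained convolutional VAE
#'
#' Allocates and initializes all weights (He initialization for the ReLU
#' convolutions, Glorot for the dense heads) from `cfg$seed`.
#'
#' @param cfg a [vae_config()].
#' @return a `vae_model` (untrained).
#' @export
build_vae <- function(cfg = vae_config()) {
  stopifnot(inherits(cfg, "vae_config"))
  a <- vae_arch(cfg)
  p <- list()
  with_local_seed(child_seed(cfg$seed, 1), {
    he <- function(fan_in, nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
    for (i in seq_len(a$n)) {
      p[[sprintf("enc%d_W1", i)]] <- he(a$K * a$cin[i], a$K * a$cin[i], a$ch[i])
      p[[sprintf("enc%d_b1", i)]] <- numeric(a$ch[i])
      p[[sprintf("enc%d_W2", i)]] <- he(a$K * a$ch[i], a$K * a$ch[i], a$ch[i])
      p[[sprintf("enc%d_b2", i)]] <- numeric(a$ch[i])
    }
    gl <- function(fi, fo) matrix(rnorm(fi * fo, 0, sqrt(1 / fi)), fi, fo)
    p$fc_mu_W <- gl(a$F, cfg$latent_dim); p$fc_mu_b <- numeric(cfg$latent_dim)
    p$fc_lv_W <- gl(a$F, cfg$latent_dim); p$fc_lv_b <- numeric(cfg$latent_dim)
    p$dec_fc_W <- gl(cfg$latent_dim, a$F); p$dec_fc_b <- numeric(a$F)
    for (j in seq_len(a$n)) {
      i <- a$n - j + 1L                 # mirrored encoder stack
      cout2 <- a$cin[i]                 # restore that stack's input channels
      p[[sprintf("dec%d_W1", j)]] <- he(a$K * a$ch[i], a$K * a$ch[i], a$ch[i])
      p[[sprintf("dec%d_b1", j)]] <- numeric(a$ch[i])
      p[[sprintf("dec%d_W2", j)]] <- he(a$K * a$ch[i], a$K * a$ch[i], cout2)
      p[[sprintf("dec%d_b2", j)]] <- numeric(cout2)
    }
  })
  structure(list(cfg = cfg, arch = a, params = p, trained = FALSE,
                 loss_report = NULL, split = NULL),
            class = "vae_model")
}

#' @export
print.vae_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<vae_model> Nconv=%d Ld=%d (%s, %d parameters)\n",
              x$cfg$n_conv, x$cfg$latent_dim,
              if (x$trained) "trained" else "untrained", np))
  invisible(x)
}

vae_forward <- function(p, a, X, eps = NULL) {
  B <- nrow(X)
  cache <- list()
  # the 0-10 scaled input is centered on its offset so the first ReLU layer
  # sees zero-mean signals (the offset is restored at the output); this is a
  # reparameterization of the same network, not a change of input scale
  A <- array(X - 5, c(B, 200L, 1L))
  for (i in seq_len(a$n)) {
    c1 <- conv1d_fw(A, p[[sprintf("enc%d_W1", i)]], p[[sprintf("enc%d_b1", i)]])
    A1 <- pmax(c1$Z, 0)
    c2 <- conv1d_fw(A1, p[[sprintf("enc%d_W2", i)]], p[[sprintf("enc%d_b2", i)]])
    A2 <- pmax(c2$Z, 0)
    pl <- maxpool2_fw(A2)
    cache[[sprintf("enc%d", i)]] <- list(c1 = c1, m1 = c1$Z > 0, c2 = c2,
                                         m2 = c2$Z > 0, pool = pl$mask)
    A <- pl$P
  }
  flat <- A; dim(flat) <- c(B, a$F)
  mu <- sweep(flat %*% p$fc_mu_W, 2, p$fc_mu_b, "+")
  lv_raw <- sweep(flat %*% p$fc_lv_W, 2, p$fc_lv_b, "+")
  lv <- pmin(pmax(lv_raw, -8), 8)
  lv_mask <- lv_raw > -8 & lv_raw < 8
  if (is.null(eps)) eps <- matrix(0, B, ncol(mu))
  z <- mu + exp(0.5 * lv) * eps
  # decoder
  Hlin <- sweep(z %*% p$dec_fc_W, 2, p$dec_fc_b, "+")
  H <- pmax(Hlin, 0)
  D <- H; dim(D) <- c(B, a$L_end, a$C_end)
  dcache <- list()
  for (j in seq_len(a$n)) {
    U <- upsample2_fw(D)
    c1 <- conv1d_fw(U, p[[sprintf("dec%d_W1", j)]], p[[sprintf("dec%d_b1", j)]])
    A1 <- pmax(c1$Z, 0)
    c2 <- conv1d_fw(A1, p[[sprintf("dec%d_W2", j)]], p[[sprintf("dec%d_b2", j)]])
    last <- j == a$n
    A2 <- if (last) c2$Z else pmax(c2$Z, 0)
    dcache[[sprintf("dec%d", j)]] <- list(c1 = c1, m1 = c1$Z > 0, c2 = c2,
                                          m2 = if (last) NULL else c2$Z > 0)
    D <- A2
  }
  Xhat <- D + 5; dim(Xhat) <- c(B, 200L)
  list(Xhat = Xhat, mu = mu, lv = lv, lv_mask = lv_mask, z = z, eps = eps,
       flat = flat, H = H, Hmask = Hlin > 0, enc = cache, dec = dcache, B = B)
}

# Reconstruction is the squared-error norm over the 200-sample beat window
# (averaged over the batch); the KL term sums over latent dimensions. Keeping
# both on the per-beat (not per-sample) scale balances the two terms; a
# per-sample mean would overweight the prior 200-fold and collapse the
# posterior.
vae_losses_from_forward <- function(fw, X) {
  recon <- mean(rowSums((X - fw$Xhat)^2))
  kl <- mean(0.5 * rowSums(fw$mu^2 + exp(fw$lv) - 1 - fw$lv))
  list(total = recon + kl, recon = recon, kl = kl)
}

vae_backward <- function(p, a, X, fw) {
  B <- fw$B
  g <- list()
  dXhat <- 2 * (fw$Xhat - X) / B
  dD <- array(dXhat, c(B, 200L, 1L))
  for (j in rev(seq_len(a$n))) {
    cc <- fw$dec[[sprintf("dec%d", j)]]
    dZ2 <- if (is.null(cc$m2)) dD else dD * cc$m2
    bw2 <- conv1d_bw(dZ2, cc$c2, p[[sprintf("dec%d_W2", j)]])
    g[[sprintf("dec%d_W2", j)]] <- bw2$dW; g[[sprintf("dec%d_b2", j)]] <- bw2$db
    dZ1 <- bw2$dA * cc$m1
    bw1 <- conv1d_bw(dZ1, cc$c1, p[[sprintf("dec%d_W1", j)]])
    g[[sprintf("dec%d_W1", j)]] <- bw1$dW; g[[sprintf("dec%d_b1", j)]] <- bw1$db
    dD <- upsample2_bw(bw1$dA)
  }
  dH <- dD; dim(dH) <- c(B, a$F)
  dHlin <- dH * fw$Hmask
  g$dec_fc_W <- crossprod(fw$z, dHlin); g$dec_fc_b <- colSums(dHlin)
  dz <- dHlin %*% t(p$dec_fc_W)
  dmu <- dz + fw$mu / B
  dlv <- dz * fw$eps * 0.5 * exp(0.5 * fw$lv) + 0.5 * (exp(fw$lv) - 1) / B
  dlv <- dlv * fw$lv_mask
  g$fc_mu_W <- crossprod(fw$flat, dmu); g$fc_mu_b <- colSums(dmu)
  g$fc_lv_W <- crossprod(fw$flat, dlv); g$fc_lv_b <- colSums(dlv)
  dflat <- dmu %*% t(p$fc_mu_W) + dlv %*% t(p$fc_lv_W)
  dP <- dflat; dim(dP) <- c(B, a$L_end, a$C_end)
  for (i in rev(seq_len(a$n))) {
    cc <- fw$enc[[sprintf("enc%d", i)]]
    dA2 <- maxpool2_bw(dP, cc$pool)
    dZ2 <- dA2 * cc$m2
    bw2 <- conv1d_bw(dZ2, cc$c2, p[[sprintf("enc%d_W2", i)]])
    g[[sprintf("enc%d_W2", i)]] <- bw2$dW; g[[sprintf("enc%d_b2", i)]] <- bw2$db
    dZ1 <- bw2$dA * cc$m1
    bw1 <- conv1d_bw(dZ1, cc$c1, p[[sprintf("enc%d_W1", i)]])
    g[[sprintf("enc%d_W1", i)]] <- bw1$dW; g[[sprintf("enc%d_b1", i)]] <- bw1$db
    dP <- bw1$dA
  }
  g
}

adam_init <- function(p) {
  list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0), t = 0L)
}

adam_step <- function(p, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(g)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g[[nm]]^2
    mh <- st$m[[nm]] / (1 - b1^st$t)
    vh <- st$v[[nm]] / (1 - b2^st$t)
    p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(p = p, st = st)
}

#' Stratified train/validation/test split of a heartbeat matrix
#'
#' Splits per subject (each subject contributes to all three sets) with the
#' given fractions; row order within a set is randomized from `seed`.
#'
#' @param beats a [heartbeat_matrix()].
#' @param fractions train/val/test fractions summing to 1 (default 70/15/15).
#' @param seed RNG seed.
#' @return list of integer row indices `train`, `val`, `test`.
#' @export
split_heartbeats <- function(beats, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  with_local_seed(child_seed(seed, 5), {
    idx <- list(train = integer(0), val = integer(0), test = integer(0))
    for (sid in unique(beats$subject_ids)) {
      rows <- sample(which(beats$subject_ids == sid))
      n <- length(rows)
      n_tr <- round(fractions[1] * n)
      n_va <- round(fractions[2] * n)
      idx$train <- c(idx$train, rows[seq_len(n_tr)])
      idx$val <- c(idx$val, rows[n_tr + seq_len(min(n_va, n - n_tr))])
      idx$test <- c(idx$test, rows[setdiff(seq_len(n), seq_len(n_tr + n_va))])
    }
    lapply(idx, sample)
  })
}

#' Train the convolutional VAE
#'
#' Minimizes reconstruction MSE plus the KL divergence to the N(0, I) prior
#' by mini-batch Adam. The heartbeat matrix is split 70/15/15 into train,
#' validation and test sets, stratified by subject; test rows are never
#' touched during fitting. Training stops early when the validation loss has
#' not improved for `patience` epochs; the best-validation weights are
#' retained. Fully reproducible from `cfg$seed`.
#'
#' @param model a [build_vae()] model.
#' @param beats a [heartbeat_matrix()].
#' @param fractions train/val/test split fractions (default `c(.7, .15, .15)`).
#' @param verbose print per-epoch losses.
#' @return the trained `vae_model` with `loss_report` (per-epoch tibble) and
#'   `split` (row indices).
#' @export
train_vae <- function(model, beats, fractions = c(0.70, 0.15, 0.15),
                      verbose = FALSE) {
  stopifnot(inherits(model, "vae_model"), inherits(beats, "heartbeat_matrix"))
  cfg <- model$cfg; a <- model$arch
  split <- split_heartbeats(beats, fractions, seed = cfg$seed)
  if (length(split$train) < 10L * cfg$minibatch) {
    abort(sprintf("need >= %d training rows (10 mini-batches), have %d",
                  10L * cfg$minibatch, length(split$train)),
          class = "scgkit_insufficient_data_error")
  }
  X <- beats$segments
  Xval <- X[split$val, , drop = FALSE]
  p <- model$params
  st <- adam_init(p)
  best <- list(val = Inf, p = p, epoch = 0L)
  rows <- list()
  with_local_seed(child_seed(cfg$seed, 2), {
    wait <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(split$train)
      nb <- ceiling(length(ord) / cfg$minibatch)
      tr <- c(total = 0, recon = 0, kl = 0)
      for (bi in seq_len(nb)) {
        ridx <- ord[((bi - 1L) * cfg$minibatch + 1L):min(bi * cfg$minibatch, length(ord))]
        Xb <- X[ridx, , drop = FALSE]
        eps <- matrix(rnorm(length(ridx) * cfg$latent_dim), length(ridx))
        fw <- vae_forward(p, a, Xb, eps)
        ls <- vae_losses_from_forward(fw, Xb)
        if (!is.finite(ls$total)) {
          abort(sprintf("training diverged (non-finite loss at epoch %d)", ep),
                class = "scgkit_training_divergence")
        }
        g <- vae_backward(p, a, Xb, fw)
        upd <- adam_step(p, g, st, cfg$learning_rate)
        p <- upd$p; st <- upd$st
        tr <- tr + c(ls$total, ls$recon, ls$kl)
      }
      tr <- tr / nb
      vfw <- vae_forward(p, a, Xval)       # eps = 0: deterministic validation
      vls <- vae_losses_from_forward(vfw, Xval)
      rows[[ep]] <- tibble(epoch = ep, train_total = tr[["total"]],
                           train_recon = tr[["recon"]], train_kl = tr[["kl"]],
                           val_total = vls$total, val_recon = vls$recon,
                           val_kl = vls$kl)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", ep, tr[["total"]],
                        vls$total))
      }
      if (vls$total < best$val - 1e-9) {
        best <- list(val = vls$total, p = p, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  model$params <- best$p
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model$loss_report <- dplyr::bind_rows(rows)
  model$split <- split
  model$subject_ids <- beats$subject_ids
  model
}

#' Per-batch loss components of a model on given beats
#'
#' Deterministic evaluation (z = posterior mean).
#'
#' @param model a trained (or untrained) `vae_model`.
#' @param X n x 200 matrix or [heartbeat_matrix()].
#' @return list with `total`, `recon`, `kl` (`total = recon + kl`).
#' @export
vae_losses <- function(model, X) {
  if (inherits(X, "heartbeat_matrix")) X <- X$segments
  fw <- vae_forward(model$params, model$arch, X)
  vae_losses_from_forward(fw, X)
}

#' Encode beats into the latent space
#'
#' Returns the posterior mean and log-variance per beat plus one
#' reparameterized sample; the means are what downstream clustering uses.
#'
#' @param model a trained `vae_model`.
#' @param beats a [heartbeat_matrix()] or n x 200 matrix.
#' @param subject_ids optional per-row labels (taken from `beats` if a
#'   heartbeat matrix).
#' @return a `latent_codes` object: `mu`, `log_var`, `z` (n x Ld matrices),
#'   `subject_ids`.
#' @export
encode_beats <- function(model, beats, subject_ids = NULL) {
  stopifnot(inherits(model, "vae_model"))
  if (inherits(beats, "heartbeat_matrix")) {
    subject_ids <- subject_ids %||% beats$subject_ids
    beats <- beats$segments
  }
  if (ncol(beats) != 200L) {
    abort("beat rows must have exactly 200 samples", class = "scgkit_shape_error")
  }
  eps <- with_local_seed(child_seed(model$cfg$seed, 9),
                         matrix(rnorm(nrow(beats) * model$cfg$latent_dim),
                                nrow(beats)))
  fw <- vae_forward(model$params, model$arch, beats, eps)
  structure(list(mu = fw$mu, log_var = fw$lv, z = fw$z,
                 subject_ids = subject_ids %||% rep(NA_character_, nrow(beats))),
            class = "latent_codes")
}

#' @export
print.latent_codes <- function(x, ...) {
  cat(sprintf("<latent_codes> %d beats x Ld=%d\n", nrow(x$mu), ncol(x$mu)))
  invisible(x)
}

#' @export
as_tibble.latent_codes <- function(x, ...) {
  mu <- as.data.frame(x$mu)
  names(mu) <- sprintf("mu%d", seq_len(ncol(mu)))
  tibble(subject_id = x$subject_ids, !!!mu)
}

#' Reconstruct beats through the trained VAE (z = posterior mean)
#'
#' @param model a trained `vae_model`.
#' @param beats a [heartbeat_matrix()] or n x 200 matrix.
#' @return n x 200 matrix of reconstructions.
#' @export
reconstruct_beats <- function(model, beats) {
  if (inherits(beats, "heartbeat_matrix")) beats <- beats$segments
  vae_forward(model$params, model$arch, beats)$Xhat
}

#' @rdname train_vae
#' @param x a `vae_model`.
#' @param ... unused.
#' @export
tidy.vae_model <- function(x, ...) {
  if (is.null(x$loss_report)) {
    abort("model is untrained: no loss trajectory to tidy",
          class = "scgkit_argument_error")
  }
  tidyr::pivot_longer(x$loss_report, -"epoch",
                      names_to = c("set", "component"), names_sep = "_",
                      values_to = "loss")
}

#' @rdname train_vae
#' @export
glance.vae_model <- function(x, ...) {
  lr <- x$loss_report
  tibble(n_conv = x$cfg$n_conv, latent_dim = x$cfg$latent_dim,
         n_params = sum(vapply(x$params, length, integer(1))),
         epochs_run = if (is.null(lr)) 0L else nrow(lr),
         best_epoch = x$best_epoch %||% NA_integer_,
         val_loss = if (is.null(lr)) NA_real_ else min(lr$val_total),
         train_loss = if (is.null(lr)) NA_real_ else lr$train_total[nrow(lr)])
}
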