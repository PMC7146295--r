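# ggplot2 views of the main result types.

#' @export
autoplot.scg_detection <- function(object, window_s = NULL, ...) {
  t_s <- (seq_along(object$xz) - 1) / object$fs
  df <- tibble(time_s = t_s, xz = object$xz)
  ann <- object$annotations
  if (!is.null(window_s)) {
    df <- dplyr::filter(df, .data$time_s >= window_s[1], .data$time_s <= window_s[2])
    ann <- dplyr::filter(ann, .data$time_s >= window_s[1], .data$time_s <= window_s[2])
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$xz)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(data = ann, ggplot2::aes(xintercept = .data$time_s),
                        colour = "red", linetype = 2, alpha = 0.6) +
    ggplot2::labs(x = "time [s]", y = "z-scored SCG",
                  title = sprintf("Annotated heartbeats (%d beats)", nrow(object$annotations)))
}

#' @export
autoplot.bland_altman <- function(object, ...) {
  mu <- attr(object, "mu_e"); ts <- attr(object, "two_sigma")
  ggplot2::ggplot(object, ggplot2::aes(.data$mean_ms, .data$error_ms)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = mu, colour = "black") +
    ggplot2::geom_hline(yintercept = mu + c(-ts, ts), colour = "blue",
                        linetype = 3) +
    ggplot2::labs(x = "(tRR + tCC) / 2 [ms]", y = "error tRR - tCC [ms]",
                  title = "Bland-Altman interval agreement")
}

#' @export
autoplot.vae_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$epoch, .data$loss, colour = .data$set,
                               linetype = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", title = "VAE training trajectory")
}

#' @export
autoplot.latent_codes <- function(object, dims = c(1, 2), ...) {
  df <- tibble(x = object$mu[, dims[1]], y = object$mu[, dims[2]],
               subject = object$subject_ids)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$subject)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = sprintf("mu[%d]", dims[1]), y = sprintf("mu[%d]", dims[2]),
                  title = "Latent posterior means")
}

#' @export
autoplot.arch_sweep <- function(object, metric = "adjusted_rand", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$ld, .data[[metric]],
                               colour = factor(.data$n_conv))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "latent dimension Ld", y = metric, colour = "Nconv",
                  title = "Clustering quality by architecture")
}

#' @export
autoplot.k_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$k, .data$f1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "threshold multiplier k", y = "F1",
                  title = "Detection F1 vs k")
}
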