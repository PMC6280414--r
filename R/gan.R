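# Dynamic GAN for tabular minority-class oversampling.
#
# Generator: noise -> ReLU hidden layer -> sigmoid output in [0,1]^d.
# Discriminator: sample -> 2-piece Maxout hidden layer -> sigmoid scalar.
# Both trained by plain minibatch gradient descent on the original minimax
# objective; features are min-max scaled to [0,1] before training and
# inverse-transformed on generation.

#' GAN training configuration
#'
#' @param hidden_nodes hidden-layer width of both networks (default 100).
#' @param learning_rate gradient-descent step size (default 0.01).
#' @param epochs passes over the minority chunk (default 500).
#' @param batch_size minibatch size (default 32, capped at the sample count).
#' @param keep_d,keep_g dropout keep-probabilities of the discriminator and
#'   generator hidden layers (defaults 0.9 and 0.9: both networks keep 90%
#'   of their units during training; inverted dropout, inference uses the
#'   full network).
#' @param noise_dim noise dimension; `NULL` (default) uses the data
#'   dimension, matching a noise block of the same size as the target chunk.
#' @param noise one of `"gaussian"` (default) or `"uniform"` prior.
#' @param momentum optional gradient-descent momentum in `[0, 1)` (default 0).
#' @param early_stop stop when the mean discriminator output stays within
#'   0.05 of 1/2 for 10 consecutive epochs after a burn-in of
#'   `min_epochs` (default `FALSE`: run all epochs).
#' @param min_epochs burn-in before early stopping may trigger (default 100).
#' @return a `gan_config` list.
#' @export
gan_config <- function(hidden_nodes = 100, learning_rate = 0.01,
                       epochs = 500, batch_size = 32,
                       keep_d = 0.9, keep_g = 0.9,
                       noise_dim = NULL, noise = c("gaussian", "uniform"),
                       momentum = 0, early_stop = FALSE, min_epochs = 100) {
  noise <- match.arg(noise)
  if (hidden_nodes < 1) stop_pgm("hidden_nodes must be >= 1", class = "pgmelm_spec_error")
  if (learning_rate <= 0) stop_pgm("learning_rate must be positive", class = "pgmelm_spec_error")
  if (keep_d <= 0 || keep_d > 1 || keep_g <= 0 || keep_g > 1) {
    stop_pgm("keep probabilities must lie in (0, 1]", class = "pgmelm_spec_error")
  }
  if (momentum < 0 || momentum >= 1) {
    stop_pgm("momentum must lie in [0, 1)", class = "pgmelm_spec_error")
  }
  structure(list(hidden_nodes = hidden_nodes, learning_rate = learning_rate,
                 epochs = epochs, batch_size = batch_size,
                 keep_d = keep_d, keep_g = keep_g, noise_dim = noise_dim,
                 noise = noise, momentum = momentum,
                 early_stop = early_stop, min_epochs = min_epochs),
            class = "gan_config")
}

draw_noise <- function(n, dim, kind) {
  if (kind == "uniform") matrix(stats::runif(n * dim, -1, 1), n)
  else matrix(stats::rnorm(n * dim), n)
}

gan_d_forward <- function(p, X, mask = NULL) {
  A1 <- sweep(X %*% p$U1, 2, p$c1, "+")
  A2 <- sweep(X %*% p$U2, 2, p$c2, "+")
  H <- pmax(A1, A2)                       # 2-piece maxout
  if (!is.null(mask)) H <- H * mask
  list(p = sigmoid(drop(H %*% p$w) + p$b), H = H, which1 = A1 >= A2)
}

gan_g_forward <- function(p, Z, mask = NULL) {
  A <- sweep(Z %*% p$W1, 2, p$b1, "+")
  Hg <- pmax(A, 0)                        # ReLU
  if (!is.null(mask)) Hg <- Hg * mask
  list(out = sigmoid(sweep(Hg %*% p$W2, 2, p$b2, "+")), Hg = Hg, A = A)
}

#' Train a GAN on the minority-class chunk
#'
#' Alternates one discriminator ascent step on
#' \eqn{\overline{\log D(x)} + \overline{\log(1 - D(G(z)))}} and one
#' generator descent step on \eqn{\overline{\log(1 - D(G(z)))}} per
#' minibatch. At the saddle point the discriminator cannot tell real from
#' generated and its mean output approaches 1/2; the per-epoch trace records
#' both losses and the mean discriminator output on a mixed real + generated
#' batch so convergence can be inspected.
#'
#' @param X_min minority-class feature matrix (>= 2 rows), typically in
#'   principal-component space.
#' @param config a [gan_config()].
#' @param seed integer seed; the full parameter trajectory is reproducible.
#' @return object of class `dynamic_gan` with fields `theta_g`, `theta_d`,
#'   `trace` (data frame: `epoch`, `d_loss`, `g_loss`, `mean_d`), `scale`
#'   (min-max bounds), `d` (data dimension), `config`, `epochs_run`.
#' @export
train_dynamic_gan <- function(X_min, config = gan_config(), seed = 1) {
  X_min <- check_matrix(X_min)
  if (nrow(X_min) < 2) {
    stop_pgm("GAN training needs at least 2 minority samples",
             class = "pgmelm_insufficient_data")
  }
  set.seed(as.integer(seed))
  d <- ncol(X_min); n <- nrow(X_min)
  nh <- config$hidden_nodes
  nz <- if (is.null(config$noise_dim)) d else config$noise_dim
  lr <- config$learning_rate
  batch <- min(config$batch_size, n)
  lo <- apply(X_min, 2, min); hi <- apply(X_min, 2, max)
  rng <- pmax(hi - lo, .Machine$double.eps)
  Xs <- sweep(sweep(X_min, 2, lo), 2, rng, "/")
  g <- list(W1 = matrix(stats::rnorm(nz * nh), nz, nh), b1 = rep(0, nh),
            W2 = matrix(stats::rnorm(nh * d, sd = 0.1), nh, d), b2 = rep(0, d))
  dp <- list(U1 = matrix(stats::rnorm(d * nh, sd = 0.1), d, nh), c1 = rep(0, nh),
             U2 = matrix(stats::rnorm(d * nh, sd = 0.1), d, nh), c2 = rep(0, nh),
             w = stats::rnorm(nh, sd = 0.1), b = 0)
  vel_g <- lapply(g, function(p) p * 0)
  vel_d <- lapply(dp, function(p) p * 0)
  mom <- config$momentum
  tr_d_loss <- tr_g_loss <- tr_mean_d <- numeric(config$epochs)
  epochs_run <- 0L
  in_band <- 0L
  for (ep in seq_len(config$epochs)) {
    idx <- sample.int(n)
    for (st in seq(1, n, by = batch)) {
      ib <- idx[st:min(st + batch - 1, n)]
      nb <- length(ib)
      Xb <- Xs[ib, , drop = FALSE]
      # ---- discriminator ascent ----
      Z <- draw_noise(nb, nz, config$noise)
      mg <- matrix(stats::rbinom(nb * nh, 1, config$keep_g) / config$keep_g, nb)
      Xfake <- gan_g_forward(g, Z, mg)$out
      md1 <- matrix(stats::rbinom(nb * nh, 1, config$keep_d) / config$keep_d, nb)
      md2 <- matrix(stats::rbinom(nb * nh, 1, config$keep_d) / config$keep_d, nb)
      fr <- gan_d_forward(dp, Xb, md1)
      ff <- gan_d_forward(dp, Xfake, md2)
      er <- (1 - fr$p) / nb                  # d/dlogit of mean log D(x)
      ef <- (-ff$p) / nb                     # d/dlogit of mean log(1 - D(fake))
      dback <- function(fw, e, mask, Xin) {
        dH <- outer(e, dp$w) * mask
        d1 <- dH * fw$which1; d2 <- dH * (!fw$which1)
        list(U1 = crossprod(Xin, d1), c1 = colSums(d1),
             U2 = crossprod(Xin, d2), c2 = colSums(d2))
      }
      br <- dback(fr, er, md1, Xb)
      bf <- dback(ff, ef, md2, Xfake)
      gd <- list(U1 = br$U1 + bf$U1, c1 = br$c1 + bf$c1,
                 U2 = br$U2 + bf$U2, c2 = br$c2 + bf$c2,
                 w = drop(crossprod(fr$H, er) + crossprod(ff$H, ef)),
                 b = sum(er) + sum(ef))
      for (nm in names(dp)) {               # ascent
        vel_d[[nm]] <- mom * vel_d[[nm]] + lr * gd[[nm]]
        dp[[nm]] <- dp[[nm]] + vel_d[[nm]]
      }
      # ---- generator descent on log(1 - D(G(z))) ----
      Z <- draw_noise(nb, nz, config$noise)
      mg <- matrix(stats::rbinom(nb * nh, 1, config$keep_g) / config$keep_g, nb)
      gf <- gan_g_forward(g, Z, mg)
      ff <- gan_d_forward(dp, gf$out)
      e <- (-ff$p) / nb
      dHd <- outer(e, dp$w)
      dx <- (dHd * ff$which1) %*% t(dp$U1) + (dHd * (!ff$which1)) %*% t(dp$U2)
      dout <- dx * gf$out * (1 - gf$out)
      gg <- list(W1 = crossprod(Z, (dout %*% t(g$W2)) * mg * (gf$A > 0)),
                 b1 = colSums((dout %*% t(g$W2)) * mg * (gf$A > 0)),
                 W2 = crossprod(gf$Hg, dout), b2 = colSums(dout))
      for (nm in names(g)) {                # descent
        vel_g[[nm]] <- mom * vel_g[[nm]] - lr * gg[[nm]]
        g[[nm]] <- g[[nm]] + vel_g[[nm]]
      }
    }
    # ---- epoch trace on full batches, no dropout ----
    Zt <- draw_noise(n, nz, config$noise)
    fake <- gan_g_forward(g, Zt)$out
    p_real <- gan_d_forward(dp, Xs)$p
    p_fake <- gan_d_forward(dp, fake)$p
    eps <- 1e-12
    d_loss <- mean(log(p_real + eps)) + mean(log(1 - p_fake + eps))
    g_loss <- mean(log(1 - p_fake + eps))
    mean_d <- mean(c(p_real, p_fake))
    if (!is.finite(d_loss) || !is.finite(g_loss)) {
      stop_pgm("GAN training diverged at epoch %d", ep,
               class = "pgmelm_divergence_error")
    }
    tr_d_loss[ep] <- d_loss; tr_g_loss[ep] <- g_loss; tr_mean_d[ep] <- mean_d
    epochs_run <- ep
    if (config$early_stop && ep > config$min_epochs) {
      in_band <- if (abs(mean_d - 0.5) < 0.05) in_band + 1L else 0L
      if (in_band >= 10L) break
    }
  }
  keep <- seq_len(epochs_run)
  trace <- data.frame(epoch = keep, d_loss = tr_d_loss[keep],
                      g_loss = tr_g_loss[keep], mean_d = tr_mean_d[keep])
  structure(list(theta_g = g, theta_d = dp, trace = trace,
                 scale = list(lo = lo, hi = hi, rng = rng), d = d,
                 noise_dim = nz, config = config, seed = as.integer(seed),
                 epochs_run = epochs_run),
            class = "dynamic_gan")
}

#' @export
print.dynamic_gan <- function(x, ...) {
  cat(sprintf("<dynamic_gan> dim %d, %d hidden nodes, %d epochs, final mean D = %.3f\n",
              x$d, x$config$hidden_nodes, x$epochs_run,
              utils::tail(x$trace$mean_d, 1)))
  invisible(x)
}

#' Sample synthetic minority rows from a trained GAN
#'
#' @param model a trained `dynamic_gan`.
#' @param count number of rows to draw (0 gives an empty matrix with the
#'   right number of columns).
#' @param seed integer seed; the same seed reproduces the same samples.
#' @return `count x d` matrix on the original feature scale.
#' @export
generate_minority <- function(model, count, seed = 1) {
  if (!inherits(model, "dynamic_gan")) {
    stop_pgm("model must be a trained dynamic_gan", class = "pgmelm_state_error")
  }
  if (count < 0) stop_pgm("count must be nonnegative", class = "pgmelm_spec_error")
  if (count == 0) return(matrix(numeric(0), 0, model$d))
  set.seed(as.integer(seed))
  Z <- draw_noise(count, model$noise_dim, model$config$noise)
  out <- gan_g_forward(model$theta_g, Z)$out
  sweep(sweep(out, 2, model$scale$rng, "*"), 2, model$scale$lo, "+")
}

#' Mean discriminator output on a mixed real + generated batch
#'
#' Diagnostic for GAN convergence: near the saddle point the discriminator
#' assigns about 1/2 everywhere.
#'
#' @param model a trained `dynamic_gan`.
#' @param X_real real samples on the original feature scale.
#' @param seed seed for the generated half of the batch.
#' @return scalar in `(0, 1)`.
#' @export
discriminator_balance <- function(model, X_real, seed = 1) {
  X_real <- check_matrix(X_real)
  Xs <- sweep(sweep(X_real, 2, model$scale$lo), 2, model$scale$rng, "/")
  fake_raw <- generate_minority(model, nrow(X_real), seed)
  fs <- sweep(sweep(fake_raw, 2, model$scale$lo), 2, model$scale$rng, "/")
  mean(c(gan_d_forward(model$theta_d, Xs)$p,
         gan_d_forward(model$theta_d, fs)$p))
}
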