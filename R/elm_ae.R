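# ELM autoencoder: l1-penalized reconstruction solved with FISTA.

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit an ELM autoencoder layer with FISTA
#'
#' Learns output weights \eqn{\beta} that reconstruct the input from a random
#' orthogonal hidden projection by minimizing
#' \eqn{\|H\beta - X\|_F^2 + \lambda \|\beta\|_{\ell_1}}, via the fast
#' iterative shrinkage-thresholding algorithm (FISTA) with step size
#' \eqn{1/L}, where \eqn{L = 2\sigma_{max}(H)^2} is the Lipschitz constant
#' of the smooth part's gradient. The learned \eqn{\beta} (one row per
#' hidden node) is later used as a deterministic feature map
#' \eqn{X \mapsto g(X \beta^\top)}.
#'
#' @param X input matrix to reconstruct.
#' @param n_hidden hidden-node count of the autoencoder.
#' @param l1 nonnegative \eqn{\ell_1} penalty weight (default `1e-3`).
#' @param iters FISTA iterations (default 50).
#' @param seed integer seed for the random projection.
#' @return object of class `elm_ae`: fields `beta` (`n_hidden x d`), `layer`
#'   (the random projection), `objective` (per-iteration trace), `l1`.
#' @export
elm_ae_fit <- function(X, n_hidden, l1 = 1e-3, iters = 50, seed = 1) {
  X <- check_matrix(X)
  if (n_hidden < 1) stop_pgm("n_hidden must be >= 1", class = "pgmelm_spec_error")
  if (l1 < 0) stop_pgm("l1 must be nonnegative", class = "pgmelm_spec_error")
  layer <- random_layer(ncol(X), n_hidden, seed)
  H <- hidden_output(X, layer)
  L <- 2 * max(svd(H, nu = 0, nv = 0)$d)^2
  if (L <= 0) L <- 1
  step <- 1 / L
  obj <- function(B) sum((H %*% B - X)^2) + l1 * sum(abs(B))
  B <- matrix(0, n_hidden, ncol(X))
  Yk <- B; tk <- 1
  trace <- numeric(iters)
  HtH <- crossprod(H); HtX <- crossprod(H, X)
  for (k in seq_len(iters)) {
    grad <- 2 * (HtH %*% Yk - HtX)
    B_new <- soft_threshold(Yk - step * grad, step * l1)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Yk <- B_new + ((tk - 1) / t_new) * (B_new - B)
    B <- B_new; tk <- t_new
    trace[k] <- obj(B)
    if (!is.finite(trace[k])) {
      stop_pgm("FISTA objective diverged at iteration %d", k,
               class = "pgmelm_step_size_error")
    }
  }
  structure(list(beta = B, layer = layer, objective = trace, l1 = l1,
                 n_hidden = n_hidden, d = ncol(X), seed = as.integer(seed)),
            class = "elm_ae")
}

#' @export
print.elm_ae <- function(x, ...) {
  cat(sprintf("<elm_ae> %d -> %d nodes, l1 = %g, final objective %.4g\n",
              x$d, x$n_hidden, x$l1, utils::tail(x$objective, 1)))
  invisible(x)
}

ae_transform <- function(ae, X) sigmoid(X %*% t(ae$beta))
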