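# Hierarchical ELM: stacked ELM-AE feature layers + supervised ELM decision.

#' Forward pass through stacked feature layers
#'
#' Applies the learned autoencoder feature maps layer by layer:
#' \eqn{H_i = g(H_{i-1} \beta_i^\top)}, with sigmoid \eqn{g}. Every feature
#' layer keeps the same node count as its predecessor.
#'
#' @param model a fitted `helm_model` or `pgmelm_model`.
#' @param X input matrix in the model's original feature space.
#' @return the final hidden representation (columns = nodes of last layer).
#' @export
helm_forward <- function(model, X) {
  X <- check_matrix(X)
  if (ncol(X) != model$d) {
    stop_pgm("expected %d features, got %d", model$d, ncol(X),
             class = "pgmelm_shape_error")
  }
  H <- X
  for (ae in model$feature_layers) H <- ae_transform(ae, H)
  H
}

#' Fit a hierarchical ELM (H-ELM) classifier
#'
#' Unsupervised feature learning by a stack of \eqn{\ell_1}-regularized ELM
#' autoencoders, followed by a supervised single-layer ELM decision stage on
#' the last representation. The default structure is two feature layers of
#' `ceiling(N / M)` nodes, mirroring the node rule of the adaptive model in
#' the no-rebalancing limit.
#'
#' @param X training feature matrix.
#' @param y binary labels (minority = 1).
#' @param n_layers number of autoencoder feature layers (default 2).
#' @param n_hidden nodes per layer; default `ceiling(nrow(X) / ncol(X))`.
#' @param C ridge coefficient of the decision layer (default 1).
#' @param l1,iters autoencoder penalty and FISTA iterations, see
#'   [elm_ae_fit()].
#' @param seed integer seed; per-layer seeds are derived from it.
#' @return object of class `helm_model`.
#' @export
helm_fit <- function(X, y, n_layers = 2, n_hidden = NULL, C = 1,
                     l1 = 1e-3, iters = 50, seed = 1) {
  X <- check_matrix(X); y <- check_binary_labels(y)
  if (is.null(n_hidden)) n_hidden <- max(1L, ceiling(nrow(X) / ncol(X)))
  if (n_layers < 1 || n_hidden < 1) {
    stop_pgm("n_layers and n_hidden must be >= 1", class = "pgmelm_structure_error")
  }
  feature_layers <- vector("list", n_layers)
  H <- X
  for (q in seq_len(n_layers)) {
    ae <- elm_ae_fit(H, n_hidden, l1 = l1, iters = iters,
                     seed = derive_seed(seed, q))
    feature_layers[[q]] <- ae
    H <- ae_transform(ae, H)
  }
  dec_layer <- random_layer(ncol(H), n_hidden, derive_seed(seed, n_layers + 1L))
  Hd <- hidden_output(H, dec_layer)
  beta <- elm_solve(Hd, y, C)
  structure(list(feature_layers = feature_layers, decision = dec_layer,
                 beta = beta, C = C, d = ncol(X), n_hidden = n_hidden,
                 n_layers = n_layers, seed = as.integer(seed)),
            class = "helm_model")
}

#' @rdname predict.elm_model
#' @export
predict.helm_model <- function(object, X, ...) {
  H <- helm_forward(object, X)
  scores <- drop(hidden_output(H, object$decision) %*% object$beta)
  list(scores = scores, labels = as.integer(scores >= 0.5))
}

#' @export
print.helm_model <- function(x, ...) {
  cat(sprintf("<helm_model> %d inputs, %d feature layers x %d nodes + decision layer (C = %g)\n",
              x$d, x$n_layers, x$n_hidden, x$C))
  invisible(x)
}
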