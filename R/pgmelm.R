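# Self-adaptive multilayer ELM (PGM-ELM): structure rule + stacked fit +
# full pipeline (standardize -> PCA -> dynamic GAN -> multilayer ELM).

#' Self-adaptive hidden structure from the balancing outcome
#'
#' The hidden-node count interpolates between the raw and the balanced
#' sample/feature ratios according to how much the class ratio moved:
#' \eqn{P = \lceil (1 - \Delta IR) N/M + \Delta IR \cdot N'/M' \rceil}, and
#' the hidden-layer count grows with the rebalancing effort,
#' \eqn{Q = \lceil \Delta IR \cdot M' \rceil}, clamped to at least 1 so a
#' model always exists (with \eqn{\Delta IR = 0} the rule alone would give
#' 0 layers).
#'
#' @param n,m training-sample and feature counts before balancing.
#' @param n_prime,m_prime sample count after balancing and retained
#'   principal-component count.
#' @param d_ir change in imbalance ratio, in `[0, 1)`; see [delta_ir()].
#' @return list with integers `P` (nodes per hidden layer) and `Q`
#'   (hidden-layer count).
#' @examples
#' adaptive_structure(100, 20, 160, 5, 0.75)  # P = 26, Q = 4
#' @export
adaptive_structure <- function(n, m, n_prime, m_prime, d_ir) {
  if (min(n, m, n_prime, m_prime) < 1) {
    stop_pgm("all counts must be >= 1", class = "pgmelm_structure_error")
  }
  if (d_ir < 0 || d_ir >= 1) {
    stop_pgm("delta IR must lie in [0, 1)", class = "pgmelm_structure_error")
  }
  P <- as.integer(ceiling((1 - d_ir) * n / m + d_ir * n_prime / m_prime))
  Q <- max(1L, as.integer(ceiling(d_ir * m_prime)))
  list(P = P, Q = Q)
}

#' Fit the multilayer ELM classifier on a balanced dataset
#'
#' Builds `Q` unsupervised ELM-autoencoder feature layers of `P` nodes each
#' (sigmoid activation throughout), then a supervised decision layer on the
#' last representation: orthogonal random input weights and bias, and a
#' closed-form ridge solve against targets 1 (minority) / 0 (majority).
#'
#' @param Z feature matrix of the balanced training set (principal-component
#'   space in the full pipeline).
#' @param y binary labels.
#' @param P nodes per hidden layer; `Q` hidden-layer count — typically from
#'   [adaptive_structure()].
#' @param Q integer number of feature layers.
#' @param C ridge coefficient (default 1).
#' @param l1,iters autoencoder penalty and FISTA iterations.
#' @param seed integer seed; all layer randomness derives from it.
#' @return object of class `pgmelm_model` (layer list of length `Q + 1`:
#'   `Q` autoencoders plus the decision layer).
#' @export
pgmelm_fit <- function(Z, y, P, Q, C = 1, l1 = 1e-3, iters = 50, seed = 1) {
  Z <- check_matrix(Z); y <- check_binary_labels(y)
  if (P < 1 || Q < 1) {
    stop_pgm("P and Q must be >= 1 (got P = %s, Q = %s)", P, Q,
             class = "pgmelm_structure_error")
  }
  feature_layers <- vector("list", Q)
  H <- Z
  for (q in seq_len(Q)) {
    ae <- elm_ae_fit(H, P, l1 = l1, iters = iters, seed = derive_seed(seed, q))
    feature_layers[[q]] <- ae
    H <- ae_transform(ae, H)
  }
  dec_layer <- random_layer(ncol(H), P, derive_seed(seed, Q + 1L))
  Hd <- hidden_output(H, dec_layer)
  beta <- elm_solve(Hd, y, C)
  structure(list(feature_layers = feature_layers, decision = dec_layer,
                 beta = beta, P = as.integer(P), Q = as.integer(Q), C = C,
                 d = ncol(Z), seed = as.integer(seed)),
            class = c("pgmelm_model", "helm_model"))
}

#' @export
print.pgmelm_model <- function(x, ...) {
  cat(sprintf("<pgmelm_model> %d inputs, Q = %d layers x P = %d nodes + decision layer (C = %g)\n",
              x$d, x$Q, x$P, x$C))
  invisible(x)
}

#' Fit the full PGM-ELM pipeline
#'
#' End-to-end training on a raw imbalanced dataset: (1) z-score the
#' features; (2) reduce to principal components under the cumulative
#' contribution `threshold`; (3) balance the classes with the dynamically
#' repeated GAN; (4) choose the hidden structure (P, Q) from the balancing
#' outcome; (5) fit the multilayer ELM. Test samples are transformed with
#' the training-set standardizer and eigenvectors (no refitting).
#'
#' @param ds an [imb_dataset] of raw training features.
#' @param threshold PCA cumulative-contribution cutoff (default 0.85).
#' @param config a [gan_config()].
#' @param C ridge coefficient (default 1).
#' @param l1,iters autoencoder settings, see [elm_ae_fit()].
#' @param seed integer master seed; standardizer and PCA are deterministic,
#'   GAN and layer seeds derive from it.
#' @return object of class `pgmelm_pipeline` bundling `scaler`, `pca`,
#'   `balanced` (the `balanced_dataset`), `structure` (P, Q, and the counts
#'   that produced them), and `model` (the `pgmelm_model`).
#' @export
pgmelm <- function(ds, threshold = 0.85, config = gan_config(), C = 1,
                   l1 = 1e-3, iters = 50, seed = 1) {
  stopifnot(inherits(ds, "imb_dataset"))
  scaler <- standardizer_fit(ds$X)
  Xs <- standardizer_apply(scaler, ds$X)
  pca <- pca_fit(Xs, threshold)
  Z <- pca_transform(pca, Xs)
  ds_pc <- imb_dataset(Z, ds$y)
  bal <- balance_dataset(ds_pc, config, seed = derive_seed(seed, 101L))
  st <- adaptive_structure(ds$n, ds$m, bal$n_prime, pca$m_prime, bal$delta_ir)
  model <- pgmelm_fit(bal$X, bal$y, st$P, st$Q, C = C, l1 = l1, iters = iters,
                      seed = derive_seed(seed, 202L))
  structure(list(scaler = scaler, pca = pca, balanced = bal,
                 structure = c(st, list(n = ds$n, m = ds$m,
                                        n_prime = bal$n_prime,
                                        m_prime = pca$m_prime,
                                        delta_ir = bal$delta_ir)),
                 model = model, threshold = threshold, C = C,
                 seed = as.integer(seed)),
            class = "pgmelm_pipeline")
}

#' @export
print.pgmelm_pipeline <- function(x, ...) {
  cat(sprintf(
    "<pgmelm_pipeline> M = %d -> M' = %d PCs | N = %d -> N' = %d (delta IR %.3f) | P = %d, Q = %d\n",
    length(x$scaler$mu), x$pca$m_prime, x$structure$n, x$structure$n_prime,
    x$structure$delta_ir, x$structure$P, x$structure$Q))
  invisible(x)
}

#' @rdname predict.elm_model
#' @export
predict.pgmelm_pipeline <- function(object, X, ...) {
  Xs <- standardizer_apply(object$scaler, check_matrix(X))
  Z <- pca_transform(object$pca, Xs)
  predict(object$model, Z)
}

#' Save or load an ELM-family model
#'
#' Serializes any model object of this package (including full pipelines) to
#' a single portable file; loading reproduces predictions bit-exactly.
#'
#' @param model object to save.
#' @param path file path.
#' @return `model_save` returns `path` invisibly; `model_load` returns the
#'   restored object.
#' @export
model_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname model_save
#' @export
model_load <- function(path) readRDS(path)
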