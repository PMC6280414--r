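#' Fit a per-feature standardizer
#'
#' Learns per-feature location \eqn{\mu^{(i)}} and scale \eqn{\delta^{(i)}}
#' on a training matrix, for the z-score transform
#' \eqn{\tilde{x}^{(i)} = (x^{(i)} - \mu^{(i)}) / \delta^{(i)}}. The scale is
#' the sample standard deviation (denominator \eqn{n - 1}), so that the
#' covariance matrix of the standardized features is their correlation
#' matrix.
#'
#' @param X numeric matrix with at least 2 rows.
#' @return an object of class `standardizer` with fields `mu` and `delta`.
#' @export
standardizer_fit <- function(X) {
  X <- check_matrix(X)
  if (nrow(X) < 2) {
    stop_pgm("standardization needs at least 2 rows (got %d)", nrow(X),
             class = "pgmelm_insufficient_data")
  }
  mu <- colMeans(X)
  delta <- apply(X, 2, stats::sd)
  bad <- which(delta == 0 | !is.finite(delta))
  if (length(bad)) {
    nm <- colnames(X)[bad[1]]
    if (is.null(nm)) nm <- as.character(bad[1])
    stop_pgm("feature '%s' is constant (zero scale); drop it before standardizing",
             nm, class = "pgmelm_degenerate_feature")
  }
  structure(list(mu = mu, delta = delta), class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param object a `standardizer` from [standardizer_fit()].
#' @param X matrix with the same columns as the training matrix.
#' @return the z-scored matrix.
#' @export
standardizer_apply <- function(object, X) {
  stopifnot(inherits(object, "standardizer"))
  X <- check_matrix(X)
  if (ncol(X) != length(object$mu)) {
    stop_pgm("expected %d features, got %d", length(object$mu), ncol(X),
             class = "pgmelm_shape_error")
  }
  sweep(sweep(X, 2, object$mu), 2, object$delta, "/")
}

#' Standardize a feature matrix
#'
#' Convenience wrapper: fit on `X` and transform `X`. Each output column has
#' mean 0 and unit sample variance.
#'
#' @inheritParams standardizer_fit
#' @return the z-scored matrix, with the fitted `standardizer` attached as
#'   attribute `"standardizer"`.
#' @examples
#' standardize(cbind(a = c(1, 2, 3)))  # column (-1, 0, 1)
#' @export
standardize <- function(X) {
  sc <- standardizer_fit(X)
  out <- standardizer_apply(sc, X)
  attr(out, "standardizer") <- sc
  out
}

#' Principal-component model with a cumulative-contribution cutoff
#'
#' Eigen-decomposes the sample covariance matrix
#' \eqn{R = \tilde{X}^\top \tilde{X} / (n - 1)} of a (standardized) matrix
#' and retains the smallest leading set of components whose cumulative
#' contribution rate \eqn{\alpha_r = \sum_{k \le r} \lambda_k / \sum_k
#' \lambda_k} reaches `threshold`. The default threshold of 0.85 keeps 85%
#' of total variance. Eigenvalues are clipped at zero for the contribution
#' sums; each eigenvector's sign is fixed so its largest-magnitude element
#' is positive, making the decomposition reproducible.
#'
#' @param X_std centered (typically z-scored) numeric matrix, >= 2 rows.
#' @param threshold cumulative contribution cutoff in `(0, 1]` (default 0.85).
#' @return an object of class `pca_model`: eigenvalues `lambda`
#'   (nonincreasing), orthonormal eigenvectors `vectors` (columns),
#'   contribution rates `contrib`, cumulative rates `cum_contrib`, retained
#'   count `m_prime`, and `threshold`.
#' @export
pca_fit <- function(X_std, threshold = 0.85) {
  X_std <- check_matrix(X_std)
  if (nrow(X_std) < 2) {
    stop_pgm("PCA needs at least 2 rows", class = "pgmelm_insufficient_data")
  }
  if (threshold <= 0 || threshold > 1) {
    stop_pgm("threshold must lie in (0, 1]", class = "pgmelm_spec_error")
  }
  R <- crossprod(X_std) / (nrow(X_std) - 1)
  eg <- eigen(R, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  if (sum(lambda) <= .Machine$double.eps * ncol(X_std)) {
    stop_pgm("input has rank 0 (all eigenvalues vanish)",
             class = "pgmelm_degenerate_feature")
  }
  V <- eg$vectors
  # deterministic sign: largest-|.| element of each eigenvector positive
  for (j in seq_len(ncol(V))) {
    piv <- which.max(abs(V[, j]))
    if (V[piv, j] < 0) V[, j] <- -V[, j]
  }
  contrib <- lambda / sum(lambda)
  cum <- cumsum(contrib)
  m_prime <- which(cum >= threshold - 1e-12)[1]
  structure(
    list(lambda = lambda, vectors = V, contrib = contrib, cum_contrib = cum,
         m_prime = as.integer(m_prime), threshold = threshold),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d -> %d components (threshold %.2f, cum. contribution %.3f)\n",
              length(x$lambda), x$m_prime, x$threshold, x$cum_contrib[x$m_prime]))
  invisible(x)
}

#' Project onto the retained principal components
#'
#' @param model a `pca_model` from [pca_fit()].
#' @param X_std matrix in the same (standardized) feature space the model was
#'   fitted on; a single row is accepted.
#' @param m_prime optionally override the number of components.
#' @return score matrix `Z` with `m_prime` columns named `PC1..`; its columns
#'   are uncorrelated with sample variances equal to the eigenvalues.
#' @export
pca_transform <- function(model, X_std, m_prime = model$m_prime) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(X_std))) X_std <- matrix(X_std, nrow = 1)
  X_std <- check_matrix(X_std)
  if (ncol(X_std) != nrow(model$vectors)) {
    stop_pgm("expected %d features, got %d", nrow(model$vectors), ncol(X_std),
             class = "pgmelm_shape_error")
  }
  Z <- X_std %*% model$vectors[, seq_len(m_prime), drop = FALSE]
  colnames(Z) <- paste0("PC", seq_len(m_prime))
  Z
}

#' Write principal-component scores as CSV
#'
#' @param Z score matrix from [pca_transform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(Z, path) {
  utils::write.csv(as.data.frame(Z), path, row.names = FALSE)
  invisible(path)
}
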