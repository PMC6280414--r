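# Single-layer ELM core: random orthogonal hidden layer + ridge solve.

#' Draw an orthogonal random hidden layer
#'
#' Input weights `a` (one column per hidden node) are obtained by
#' QR-orthogonalizing a Gaussian draw, so the columns are orthonormal when
#' the node count does not exceed the input dimension; when it does, the
#' transpose is orthonormalized instead (orthonormal rows). The bias vector
#' `b` is a Gaussian draw normalized to unit length.
#'
#' @param d input dimension.
#' @param n_hidden number of hidden nodes.
#' @param seed integer seed.
#' @return list with `a` (`d x n_hidden`) and `b` (length `n_hidden`).
#' @keywords internal
random_layer <- function(d, n_hidden, seed) {
  set.seed(as.integer(seed))
  G <- matrix(stats::rnorm(d * n_hidden), d, n_hidden)
  if (n_hidden <= d) {
    a <- qr.Q(qr(G))
  } else {
    a <- t(qr.Q(qr(t(G))))
  }
  b <- stats::rnorm(n_hidden)
  b <- b / sqrt(sum(b^2))
  list(a = a, b = b)
}

hidden_output <- function(X, layer) {
  sigmoid(sweep(X %*% layer$a, 2, layer$b, "+"))
}

#' Regularized ELM output weights
#'
#' Solves the ridge-regularized least-squares system for the output weights
#' \eqn{\beta} of an ELM given the hidden-layer output matrix `H` and the
#' target matrix `T`. Two algebraically identical forms are available: the
#' dual \eqn{\beta = H^\top (I/C + H H^\top)^{-1} T} (efficient when samples
#' are fewer than nodes) and the primal
#' \eqn{\beta = (I/C + H^\top H)^{-1} H^\top T}.
#'
#' @param H hidden-output matrix (`N x L`).
#' @param T_mat target matrix or vector (`N` rows).
#' @param C regularization coefficient, `> 0` (larger = weaker penalty).
#' @param form `"auto"` picks the cheaper of `"dual"` and `"primal"`.
#' @return the `L x p` output-weight matrix \eqn{\beta}.
#' @export
elm_solve <- function(H, T_mat, C = 1, form = c("auto", "dual", "primal")) {
  form <- match.arg(form)
  H <- check_matrix(H, "H")
  if (is.null(dim(T_mat))) T_mat <- matrix(T_mat, ncol = 1)
  T_mat <- check_matrix(T_mat, "T_mat")
  if (nrow(H) != nrow(T_mat)) {
    stop_pgm("H and T row counts differ", class = "pgmelm_shape_error")
  }
  if (!is.finite(C) || C <= 0) {
    stop_pgm("C must be a positive finite number", class = "pgmelm_spec_error")
  }
  n <- nrow(H); L <- ncol(H)
  if (form == "auto") form <- if (n <= L) "dual" else "primal"
  beta <- if (form == "dual") {
    t(H) %*% solve(diag(n) / C + tcrossprod(H), T_mat)
  } else {
    solve(diag(L) / C + crossprod(H), crossprod(H, T_mat))
  }
  if (!all(is.finite(beta))) {
    stop_pgm("non-finite output weights; check H and C",
             class = "pgmelm_numeric_error")
  }
  beta
}

#' Fit a single-hidden-layer ELM classifier
#'
#' Random orthogonal input weights and bias, sigmoid activation, and a
#' closed-form ridge solve of the output weights against targets 1
#' (minority) / 0 (majority).
#'
#' @param X training feature matrix.
#' @param y binary labels.
#' @param n_hidden hidden-node count (default 100).
#' @param C regularization coefficient (default 1).
#' @param seed integer seed for the random layer.
#' @return object of class `elm_model`.
#' @export
elm_fit <- function(X, y, n_hidden = 100, C = 1, seed = 1) {
  X <- check_matrix(X); y <- check_binary_labels(y)
  layer <- random_layer(ncol(X), n_hidden, seed)
  H <- hidden_output(X, layer)
  beta <- elm_solve(H, y, C)
  structure(list(layer = layer, beta = beta, C = C, n_hidden = n_hidden,
                 d = ncol(X), seed = as.integer(seed)),
            class = "elm_model")
}

#' Fit a weighted ELM for class-imbalanced data
#'
#' Identical to [elm_fit()] except that each training sample carries a class
#' weight inversely proportional to its class size
#' (\eqn{w_i = 1/n_{class(i)}}, so the raw weights sum to the number of
#' classes). The weights are normalized to mean 1 inside the solve, so with
#' perfectly balanced classes the fit reduces exactly to the unweighted ELM;
#' with imbalance, minority errors are up-weighted.
#'
#' @inheritParams elm_fit
#' @return object of class `elm_model` (with a `weights` field).
#' @export
welm_fit <- function(X, y, n_hidden = 100, C = 1, seed = 1) {
  X <- check_matrix(X); y <- check_binary_labels(y)
  if (length(unique(y)) < 2) {
    stop_pgm("weighted ELM needs both classes present",
             class = "pgmelm_single_class")
  }
  counts <- table(factor(y, levels = c(0L, 1L)))
  w_raw <- 1 / as.numeric(counts)[y + 1L]       # 1/n_class per sample
  w <- w_raw * length(y) / sum(w_raw)           # mean-1 normalization
  layer <- random_layer(ncol(X), n_hidden, seed)
  H <- hidden_output(X, layer)
  # primal weighted ridge: (I/C + H' W H) beta = H' W T
  HtW <- t(H * w)
  beta <- solve(diag(ncol(H)) / C + HtW %*% H, HtW %*% matrix(y, ncol = 1))
  if (!all(is.finite(beta))) {
    stop_pgm("non-finite output weights", class = "pgmelm_numeric_error")
  }
  structure(list(layer = layer, beta = beta, C = C, n_hidden = n_hidden,
                 d = ncol(X), seed = as.integer(seed), weights = w_raw),
            class = "elm_model")
}

#' Predict from an ELM-family model
#'
#' @param object a fitted `elm_model`, `helm_model` or `pgmelm_model`.
#' @param X feature matrix in the model's input space.
#' @param ... unused.
#' @return list with `scores` (raw decision-layer outputs) and `labels`
#'   (1 where `score >= 0.5`).
#' @export
predict.elm_model <- function(object, X, ...) {
  X <- check_matrix(X)
  if (ncol(X) != object$d) {
    stop_pgm("expected %d features, got %d", object$d, ncol(X),
             class = "pgmelm_shape_error")
  }
  scores <- drop(hidden_output(X, object$layer) %*% object$beta)
  list(scores = scores, labels = as.integer(scores >= 0.5))
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> %d inputs -> %d hidden nodes (C = %g%s)\n",
              x$d, x$n_hidden, x$C,
              if (!is.null(x$weights)) ", class-weighted" else ""))
  invisible(x)
}
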