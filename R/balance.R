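# Class-ratio arithmetic and dataset balancing (dynamic GAN and SMOTE).

#' Number of GAN repetitions for a given class imbalance
#'
#' The dynamic GAN is repeated \eqn{num = \lfloor N^-/N^+ \rfloor} times so
#' that the minority class grows to `num` times its size and the class ratio
#' approaches 1 without touching the majority class.
#'
#' @param n_min minority count \eqn{N^+} (>= 1).
#' @param n_maj majority count \eqn{N^-} (>= `n_min`).
#' @return integer `num >= 1`.
#' @examples
#' num_gan_runs(26, 224)  # 8
#' @export
num_gan_runs <- function(n_min, n_maj) {
  if (n_min < 1) stop_pgm("minority class is empty", class = "pgmelm_empty_minority")
  if (n_maj < n_min) {
    stop_pgm("majority count must be >= minority count", class = "pgmelm_spec_error")
  }
  as.integer(floor(n_maj / n_min))
}

#' Change in imbalance ratio induced by dynamic-GAN balancing
#'
#' Before balancing \eqn{IR = N^+/N^-}; after, the minority has
#' \eqn{\lfloor N^-/N^+ \rfloor N^+} samples, so
#' \eqn{IR' = \lfloor N^-/N^+ \rfloor N^+ / N^-} and
#' \eqn{\Delta IR = IR' - IR = (\lfloor N^-/N^+ \rfloor - 1) N^+ / N^-},
#' which always lies in `[0, 1)`.
#'
#' @inheritParams num_gan_runs
#' @return scalar \eqn{\Delta IR}.
#' @examples
#' delta_ir(26, 224)   # 0.8125
#' delta_ir(212, 357)  # 0
#' @export
delta_ir <- function(n_min, n_maj) {
  (num_gan_runs(n_min, n_maj) - 1) * n_min / n_maj
}

new_balanced <- function(X, y, mask, ds, num, method) {
  n_pos_new <- sum(y == 1L)
  structure(
    list(X = X, y = y, generated_mask = mask, method = method,
         num = num, n_prime = length(y),
         ir = ds$n_pos / ds$n_neg,
         ir_prime = n_pos_new / ds$n_neg,
         delta_ir = n_pos_new / ds$n_neg - ds$n_pos / ds$n_neg,
         n_pos_orig = ds$n_pos, n_neg = ds$n_neg),
    class = c("balanced_dataset", "imb_dataset_like")
  )
}

#' @export
print.balanced_dataset <- function(x, ...) {
  cat(sprintf(
    "<balanced_dataset> [%s] %d rows (%d synthetic) | IR %.3f -> %.3f (delta %.3f)\n",
    x$method, x$n_prime, sum(x$generated_mask), x$ir, x$ir_prime, x$delta_ir))
  invisible(x)
}

#' Balance a dataset by dynamically repeated GAN oversampling
#'
#' Trains a GAN on the whole minority chunk and draws
#' \eqn{(num - 1) \cdot N^+} synthetic minority rows, where
#' \eqn{num = \lfloor N^-/N^+ \rfloor}, growing the training set to
#' \eqn{N' = num \cdot N^+ + N^-}. Majority rows are passed through
#' untouched, so balancing loses no majority-class information. When
#' `num = 1` the dataset is already near-balanced and is returned unchanged
#' (no GAN is trained, \eqn{\Delta IR = 0}).
#'
#' @param ds an [imb_dataset], typically in principal-component space.
#' @param config a [gan_config()].
#' @param seed integer seed driving GAN training and sampling.
#' @return object of class `balanced_dataset`: fields `X`, `y`,
#'   `generated_mask`, `num`, `n_prime`, `ir`, `ir_prime`, `delta_ir`, and
#'   `gan` (the trained model, `NULL` when `num = 1`).
#' @export
balance_dataset <- function(ds, config = gan_config(), seed = 1) {
  stopifnot(inherits(ds, "imb_dataset"))
  if (ds$n_pos < 2) {
    stop_pgm("balancing needs at least 2 minority samples",
             class = "pgmelm_insufficient_data")
  }
  num <- num_gan_runs(ds$n_pos, ds$n_neg)
  if (num == 1L) {
    out <- new_balanced(ds$X, ds$y, rep(FALSE, ds$n), ds, num, "gan")
    out$gan <- NULL
    return(out)
  }
  X_min <- ds$X[ds$y == 1L, , drop = FALSE]
  gan <- train_dynamic_gan(X_min, config, seed = derive_seed(seed, 1L))
  n_new <- (num - 1L) * ds$n_pos
  X_new <- generate_minority(gan, n_new, seed = derive_seed(seed, 2L))
  colnames(X_new) <- colnames(ds$X)
  X <- rbind(ds$X, X_new)
  y <- c(ds$y, rep(1L, n_new))
  mask <- c(rep(FALSE, ds$n), rep(TRUE, n_new))
  out <- new_balanced(X, y, mask, ds, num, "gan")
  out$gan <- gan
  out
}

#' Balance a dataset by SMOTE interpolation
#'
#' Classic synthetic minority oversampling: each synthetic row is drawn on
#' the segment between a random minority sample and one of its `k` nearest
#' minority neighbours (Euclidean), at a uniform position along the segment.
#'
#' @param ds an [imb_dataset].
#' @param k neighbourhood size (default 5); must be smaller than the
#'   minority count.
#' @param target_count number of synthetic rows; default brings the minority
#'   to the same `num * N+` size that GAN balancing would reach.
#' @param seed integer seed.
#' @return a `balanced_dataset` (field `gan` absent, `method = "smote"`).
#' @export
smote_oversample <- function(ds, k = 5, target_count = NULL, seed = 1) {
  stopifnot(inherits(ds, "imb_dataset"))
  X_min <- ds$X[ds$y == 1L, , drop = FALSE]
  n_min <- nrow(X_min)
  if (k < 1 || k >= n_min) {
    stop_pgm("need 1 <= k < minority count (k = %s, minority = %d)", k, n_min,
             class = "pgmelm_neighbourhood_error")
  }
  num <- num_gan_runs(ds$n_pos, ds$n_neg)
  if (is.null(target_count)) target_count <- (num - 1L) * ds$n_pos
  if (target_count == 0) {
    return(new_balanced(ds$X, ds$y, rep(FALSE, ds$n), ds, num, "smote"))
  }
  set.seed(as.integer(seed))
  D <- as.matrix(stats::dist(X_min))
  diag(D) <- Inf
  nn <- t(matrix(apply(D, 1, function(r) order(r)[seq_len(k)]), nrow = k))
  base <- sample.int(n_min, target_count, replace = TRUE)
  nbr <- nn[cbind(base, sample.int(k, target_count, replace = TRUE))]
  u <- stats::runif(target_count)
  X_new <- X_min[base, , drop = FALSE] +
    u * (X_min[nbr, , drop = FALSE] - X_min[base, , drop = FALSE])
  colnames(X_new) <- colnames(ds$X)
  new_balanced(rbind(ds$X, X_new), c(ds$y, rep(1L, target_count)),
               c(rep(FALSE, ds$n), rep(TRUE, target_count)), ds, num, "smote")
}
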