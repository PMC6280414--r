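#' Generate a synthetic imbalanced biomedical-like feature table
#'
#' Draws two Gaussian classes in a feature space built from three blocks:
#' `n_informative` axes along which the class means are separated by
#' `class_sep`, `n_redundant` noisy linear combinations of the informative
#' axes (so that principal-component reduction has structure to find), and
#' `n_noise` pure-noise axes carrying no class signal. The regime emulated is
#' that of small clinical tables: tens to hundreds of samples, 8-30 partly
#' correlated real-valued features, minority fraction well below one half.
#'
#' @param n_min,n_maj minority (label 1) and majority (label 0) sample counts;
#'   `n_min <= n_maj`.
#' @param n_informative number of class-separating features (default 4).
#' @param n_redundant number of correlated derived features (default 3).
#' @param n_noise number of uninformative features (default 3).
#' @param class_sep distance between class means along each informative axis,
#'   in within-class standard deviations (default 2).
#' @param correlation in `[0, 1)`: how strongly a redundant feature follows
#'   its informative parents (1 would be an exact linear copy; default 0.9).
#' @param seed integer seed; identical arguments and seed give bit-identical data.
#' @return an [imb_dataset] with `IR = n_min/n_maj` exactly.
#' @examples
#' ds <- make_imbalanced(26, 224, seed = 1)
#' c(ds$n, ds$ir)  # 250, 26/224
#' @export
make_imbalanced <- function(n_min, n_maj,
                            n_informative = 4, n_redundant = 3, n_noise = 3,
                            class_sep = 2, correlation = 0.9, seed = 1) {
  if (n_min < 1 || n_maj < n_min) {
    stop_pgm("need 1 <= n_min <= n_maj (got %s, %s)", n_min, n_maj,
             class = "pgmelm_spec_error")
  }
  if (n_informative < 1 || n_redundant < 0 || n_noise < 0) {
    stop_pgm("need n_informative >= 1 and nonnegative feature counts",
             class = "pgmelm_spec_error")
  }
  if (correlation < 0 || correlation >= 1) {
    stop_pgm("correlation must lie in [0, 1)", class = "pgmelm_spec_error")
  }
  set.seed(as.integer(seed))
  n <- n_min + n_maj
  y <- rep(c(1L, 0L), c(n_min, n_maj))
  # informative block: unit-variance Gaussians, means +/- class_sep/2
  shift <- ifelse(y == 1L, class_sep / 2, -class_sep / 2)
  Xi <- matrix(stats::rnorm(n * n_informative), n) + shift
  blocks <- list(Xi)
  if (n_redundant > 0) {
    W <- matrix(stats::rnorm(n_informative * n_redundant), n_informative)
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")     # unit mixing vectors
    S <- Xi %*% W
    S <- sweep(S, 2, apply(S, 2, stats::sd), "/") # unit scale before noising
    noise_sd <- sqrt(1 / max(correlation, 1e-12)^2 - 1)
    blocks <- c(blocks, list(S + matrix(stats::rnorm(n * n_redundant,
                                                     sd = noise_sd), n)))
  }
  if (n_noise > 0) {
    blocks <- c(blocks, list(matrix(stats::rnorm(n * n_noise), n)))
  }
  X <- do.call(cbind, blocks)
  colnames(X) <- c(paste0("inf", seq_len(n_informative)),
                   if (n_redundant > 0) paste0("red", seq_len(n_redundant)),
                   if (n_noise > 0) paste0("noise", seq_len(n_noise)))
  # shuffle rows so class blocks are not contiguous
  ord <- sample.int(n)
  imb_dataset(X[ord, , drop = FALSE], y[ord])
}

#' Split a dataset into training and test sets
#'
#' Random sampling into disjoint, exhaustive train/test parts. Stratified
#' mode (the default) preserves the class ratio in both parts within one
#' sample; plain mode samples rows uniformly.
#'
#' @param ds an [imb_dataset].
#' @param n_train training-set size, `0 < n_train < ds$n`.
#' @param seed integer seed.
#' @param stratified preserve class proportions (default `TRUE`).
#' @return list with `imb_dataset` elements `train` and `test`.
#' @export
split_dataset <- function(ds, n_train, seed = 1, stratified = TRUE) {
  stopifnot(inherits(ds, "imb_dataset"))
  if (n_train <= 0 || n_train >= ds$n) {
    stop_pgm("n_train must lie strictly between 0 and %d", ds$n,
             class = "pgmelm_split_error")
  }
  set.seed(as.integer(seed))
  if (stratified) {
    idx_pos <- which(ds$y == 1L)
    idx_neg <- which(ds$y == 0L)
    k_pos <- round(n_train * ds$n_pos / ds$n)
    k_pos <- min(max(k_pos, 1L), ds$n_pos - 1L)
    k_neg <- n_train - k_pos
    if (k_neg < 1L || k_neg > ds$n_neg - 1L) {
      stop_pgm("stratified split with n_train = %d leaves a single-class part",
               n_train, class = "pgmelm_split_error")
    }
    tr <- c(sample(idx_pos, k_pos), sample(idx_neg, k_neg))
  } else {
    tr <- sample.int(ds$n, n_train)
  }
  te <- setdiff(seq_len(ds$n), tr)
  list(train = imb_dataset(ds$X[tr, , drop = FALSE], ds$y[tr]),
       test  = imb_dataset(ds$X[te, , drop = FALSE], ds$y[te]))
}
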