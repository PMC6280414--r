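# Internal helpers shared across the package.

#' Derive a reproducible child seed
#'
#' Deterministically maps a (seed, index) pair to a new 31-bit integer seed.
#' Used so that every stage of a pipeline (split, GAN, random layers, trials)
#' draws from its own stream while the whole run remains a pure function of a
#' single master seed.
#'
#' @param seed integer master seed.
#' @param index nonnegative integer stream index.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  # Lehmer-style mix; multipliers are classic MINSTD / Marsaglia constants
  s <- (s * 48271) %% m
  s <- (s + (as.numeric(index) %% m) * 69621) %% m
  as.integer((s %% (m - 1)) + 1)
}

#' Logistic (sigmoid) activation
#'
#' `g(u) = 1 / (1 + exp(-u))`, the activation used throughout the ELM stack
#' and in both GAN output layers.
#'
#' @param u numeric vector or matrix.
#' @return values in `(0, 1)` with the shape of `u`.
#' @export
sigmoid <- function(u) 1 / (1 + exp(-u))

stop_pgm <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "pgmelm_error")))
}

check_matrix <- function(X, arg = "X") {
  X <- as.matrix(X)
  if (!is.numeric(X)) {
    stop_pgm("'%s' must be a numeric matrix", arg, class = "pgmelm_type_error")
  }
  if (anyNA(X)) {
    stop_pgm("'%s' contains missing values; impute or drop them upstream",
             arg, class = "pgmelm_missing_error")
  }
  X
}

check_binary_labels <- function(y, arg = "y") {
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop_pgm("'%s' must contain only 0 (majority) and 1 (minority)", arg,
             class = "pgmelm_label_error")
  }
  y
}
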