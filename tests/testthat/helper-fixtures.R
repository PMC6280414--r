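# Shared fixtures, all generated in code under fixed seeds.

# correlated 2-D Gaussian minority chunk + held-out sample from the same law
gaussian2d <- function(n, seed, mu = c(2, -1), rho = 0.6) {
  set.seed(seed)
  L <- chol(matrix(c(1, rho, rho, 1), 2))
  matrix(stats::rnorm(2 * n), n) %*% L + matrix(mu, n, 2, byrow = TRUE)
}

# 1:9-skewed, linearly separable two-class dataset
skewed_separable <- function(n_min = 10, n_maj = 90, sep = 4, d = 5, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_min * d), n_min) + sep / 2,
             matrix(stats::rnorm(n_maj * d), n_maj) - sep / 2)
  imb_dataset(X, rep(c(1L, 0L), c(n_min, n_maj)))
}

# small GAN config for unit tests (quality-sensitive checks use defaults)
quick_gan <- function(epochs = 100, ...) gan_config(epochs = epochs, ...)

# centered matrix with an exactly prescribed sample covariance spectrum
matrix_with_spectrum <- function(lambda, n = 60, seed = 1) {
  set.seed(seed)
  p <- length(lambda)
  X <- matrix(stats::rnorm(n * p), n)
  X <- scale(X, center = TRUE, scale = FALSE)
  W <- t(chol(solve(crossprod(X) / (n - 1))))  # whitening: cov -> identity
  Xw <- X %*% W
  sweep(Xw, 2, sqrt(lambda), "*")
}
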