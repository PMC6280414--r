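test_that("standardization z-scores each feature with sample-sd scale", {
  out <- standardize(cbind(a = c(1, 2, 3)))
  expect_equal(as.numeric(out), c(-1, 0, 1))

  set.seed(11)
  X <- matrix(rnorm(200, mean = 5, sd = 3), 50)
  Xs <- standardize(X)
  expect_true(all(abs(colMeans(Xs)) < 1e-10))
  expect_equal(apply(Xs, 2, sd), rep(1, 4))

  # a column already standardized passes through unchanged
  z <- scale(rnorm(30))[, 1]
  expect_equal(as.numeric(standardize(cbind(z))), z, tolerance = 1e-12)
})

test_that("standardization rejects degenerate inputs informatively", {
  expect_error(standardize(cbind(ok = 1:5, flat = rep(5, 5))),
               class = "pgmelm_degenerate_feature")
  expect_error(standardize(cbind(ok = 1:5, flat = rep(5, 5))), "flat")
  expect_error(standardize(matrix(1, 1, 3)), class = "pgmelm_insufficient_data")
  expect_error(standardize(matrix(c(1, NA, 3), 3)), class = "pgmelm_missing_error")
})

test_that("train-set standardizer is reused on new samples without refitting", {
  set.seed(3)
  sc <- standardizer_fit(matrix(rnorm(80, 10, 2), 20))
  Xnew <- matrix(rnorm(8, 10, 2), 2)
  expect_equal(standardizer_apply(sc, Xnew),
               sweep(sweep(Xnew, 2, sc$mu), 2, sc$delta, "/"))
  expect_error(standardizer_apply(sc, matrix(0, 2, 3)),
               class = "pgmelm_shape_error")
})

test_that("component count follows the cumulative-contribution rule", {
  # spectrum {8,1,1}: cum. contributions 0.8, 0.9 -> 2 components at 0.85
  X <- matrix_with_spectrum(c(8, 1, 1))
  fit <- pca_fit(X, 0.85)
  expect_equal(fit$lambda, c(8, 1, 1), tolerance = 1e-9)
  expect_identical(fit$m_prime, 2L)

  # two perfectly correlated features: one component carries everything
  set.seed(7)
  u <- rnorm(40)
  fit2 <- pca_fit(standardize(cbind(u, 3 * u + 2)), 0.85)
  expect_identical(fit2$m_prime, 1L)
  expect_equal(fit2$contrib[1], 1, tolerance = 1e-12)

  # exactly isotropic 3-feature sample: every component contributes 1/3
  fit3 <- pca_fit(matrix_with_spectrum(c(1, 1, 1), seed = 2), 0.85)
  expect_equal(fit3$contrib, rep(1 / 3, 3), tolerance = 1e-9)
  expect_identical(fit3$m_prime, 3L)
})

test_that("eigen-decomposition matches an SVD oracle and is orthonormal", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(6:10, 1); p <- sample(3:10, 1)
    X <- scale(matrix(rnorm(n * p), n), center = TRUE, scale = FALSE)
    fit <- pca_fit(X, 1)
    sv <- svd(X)
    expect_equal(fit$lambda, c(sv$d^2 / (n - 1), rep(0, max(0, p - length(sv$d))))[seq_len(p)],
                 tolerance = 1e-8)
    G <- crossprod(fit$vectors)
    expect_equal(G, diag(p), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("projection decorrelates scores with variances equal to eigenvalues", {
  set.seed(21)
  Xs <- standardize(matrix(rnorm(300), 50) %*% matrix(rnorm(36), 6))
  fit <- pca_fit(Xs, 0.85)
  Z <- pca_transform(fit, Xs)
  expect_identical(ncol(Z), fit$m_prime)
  S <- cov(Z)
  expect_equal(diag(S), fit$lambda[seq_len(fit$m_prime)],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(S[upper.tri(S)])), 1e-8)

  # identity eigenvectors with all components kept reproduce the input
  id_fit <- fit
  id_fit$vectors <- diag(ncol(Xs))
  expect_equal(pca_transform(id_fit, Xs, m_prime = ncol(Xs)),
               as.matrix(Xs), ignore_attr = TRUE)

  # single-row transform keeps the contract
  z1 <- pca_transform(fit, Xs[1, ])
  expect_identical(dim(z1), c(1L, fit$m_prime))
  expect_error(pca_transform(fit, matrix(0, 2, 9)), class = "pgmelm_shape_error")
})

test_that("reconstruction error is nonincreasing in the component count", {
  set.seed(4)
  Xs <- standardize(matrix(rnorm(240), 40))
  fit <- pca_fit(Xs, 1)
  errs <- vapply(seq_len(6), function(r) {
    V <- fit$vectors[, seq_len(r), drop = FALSE]
    sum((Xs - Xs %*% V %*% t(V))^2)
  }, 0)
  expect_true(all(diff(errs) <= 1e-8))
  expect_lt(errs[6], 1e-16)
})

test_that("the retained spectrum is invariant to affine per-feature rescaling", {
  set.seed(9)
  X <- matrix(rnorm(200), 40, 5) %*% matrix(rnorm(25), 5)
  X2 <- sweep(sweep(X, 2, c(3, -2, 0.5, 10, 1), "*"), 2, c(1, 0, -4, 2, 7), "+")
  f1 <- pca_fit(standardize(X), 0.85)
  f2 <- pca_fit(standardize(X2), 0.85)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-8)
  expect_identical(f1$m_prime, f2$m_prime)
})

test_that("rank-0 input is rejected", {
  expect_error(pca_fit(matrix(0, 10, 3)), class = "pgmelm_degenerate_feature")
})
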