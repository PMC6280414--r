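test_that("ridge solve: dual and primal forms agree, identity limit holds", {
  # identity hidden matrix with weak regularization returns the targets
  T_mat <- matrix(c(0.2, 0.8, 0.5), 3)
  beta <- elm_solve(diag(3), T_mat, C = 1e8)
  expect_equal(beta, T_mat, tolerance = 1e-6)

  set.seed(51)
  for (i in 1:20) {
    n <- sample(3:20, 1); L <- sample(2:20, 1)
    H <- matrix(rnorm(n * L), n); T1 <- matrix(rnorm(n), n)
    expect_equal(elm_solve(H, T1, C = 1, form = "dual"),
                 elm_solve(H, T1, C = 1, form = "primal"), tolerance = 1e-8)
  }

  # weak regularization on an overdetermined system -> least squares
  H <- matrix(rnorm(18), 6, 3); T1 <- matrix(rnorm(6), 6)
  expect_equal(elm_solve(H, T1, C = 1e8), qr.solve(H, T1), tolerance = 1e-5)

  expect_error(elm_solve(H, T1, C = -1), class = "pgmelm_spec_error")
  expect_error(elm_solve(H, matrix(0, 5, 1)), class = "pgmelm_shape_error")
})

test_that("autoencoder FISTA solves the l1-reconstruction problem", {
  set.seed(53)
  X <- matrix(rnorm(100), 20, 5)

  # with no penalty the solution matches the closed-form least squares
  ae <- elm_ae_fit(X, n_hidden = 4, l1 = 0, iters = 2000, seed = 3)
  H <- pgmelm:::hidden_output(X, ae$layer)
  beta_ls <- qr.solve(H, X)
  expect_equal(ae$beta, beta_ls, tolerance = 1e-4)

  # zero input reconstructs with zero weights
  ae0 <- elm_ae_fit(matrix(0, 10, 3), n_hidden = 2, l1 = 1e-3, seed = 1)
  expect_equal(ae0$beta, matrix(0, 2, 3))

  # objective decreases over the run
  ae2 <- elm_ae_fit(X, n_hidden = 4, l1 = 1e-3, iters = 100, seed = 3)
  expect_lt(ae2$objective[100], ae2$objective[1])

  # penalty sparsifies relative to the unpenalized fit
  ae3 <- elm_ae_fit(X, n_hidden = 4, l1 = 5, iters = 500, seed = 3)
  expect_gte(sum(abs(ae3$beta) < 1e-8), sum(abs(ae$beta) < 1e-8))
})

test_that("stacked forward pass composes layerwise sigmoid projections", {
  set.seed(57)
  ds <- skewed_separable(20, 20, d = 4, seed = 5)
  m <- helm_fit(ds$X, ds$y, n_layers = 3, n_hidden = 6, seed = 9)
  X <- matrix(rnorm(20), 5, 4)
  H <- helm_forward(m, X)
  expect_identical(dim(H), c(5L, 6L))
  expect_true(all(H > 0 & H < 1))

  # explicit unrolled-loop oracle
  H_oracle <- X
  for (q in 1:3) H_oracle <- sigmoid(H_oracle %*% t(m$feature_layers[[q]]$beta))
  expect_equal(H, H_oracle)

  # single feature layer reduces to one projection + activation
  m1 <- helm_fit(ds$X, ds$y, n_layers = 1, n_hidden = 6, seed = 9)
  expect_equal(helm_forward(m1, X),
               sigmoid(X %*% t(m1$feature_layers[[1]]$beta)))
  expect_error(helm_forward(m, matrix(0, 2, 7)), class = "pgmelm_shape_error")
})

test_that("adaptive structure follows the rebalancing magnitude", {
  expect_identical(adaptive_structure(100, 20, 160, 5, 0.75), list(P = 26L, Q = 4L))
  # no rebalancing: width N/M, depth clamped up to one layer
  expect_identical(adaptive_structure(100, 20, 100, 5, 0), list(P = 5L, Q = 1L))
  expect_identical(adaptive_structure(50, 11, 432, 5, 0.8125)$Q, 5L)  # ceil(4.0625)

  # monotone in delta IR for fixed counts
  grid <- seq(0, 0.95, by = 0.05)
  PQ <- vapply(grid, function(d) unlist(adaptive_structure(100, 20, 160, 5, d)),
               c(P = 0, Q = 0))
  expect_true(all(diff(PQ["P", ]) >= 0))
  expect_true(all(diff(PQ["Q", ]) >= 0))
  expect_error(adaptive_structure(10, 2, 20, 2, 1), class = "pgmelm_structure_error")
})

test_that("weighted ELM balances class influence", {
  # raw per-sample weights sum to the number of classes
  set.seed(61)
  for (n_pos in c(3, 10, 25)) {
    ds <- skewed_separable(n_pos, 50 - n_pos, d = 3, seed = n_pos)
    m <- welm_fit(ds$X, ds$y, n_hidden = 10, seed = 1)
    expect_equal(sum(m$weights), 2)
  }

  # perfectly balanced labels reduce exactly to the unweighted ELM
  ds_bal <- skewed_separable(25, 25, d = 3, seed = 4)
  mw <- welm_fit(ds_bal$X, ds_bal$y, n_hidden = 12, C = 2, seed = 8)
  mu <- elm_fit(ds_bal$X, ds_bal$y, n_hidden = 12, C = 2, seed = 8)
  expect_equal(mw$beta, mu$beta, tolerance = 1e-10)

  expect_error(welm_fit(ds_bal$X, rep(1L, 50)), class = "pgmelm_single_class")
})

test_that("class weighting does not hurt minority recall on skewed data", {
  tpr_pair <- vapply(1:5, function(s) {
    ds <- skewed_separable(10, 90, sep = 2, seed = 300 + s)
    parts <- split_dataset(ds, 70, seed = s)
    sc <- standardizer_fit(parts$train$X)
    Xtr <- standardizer_apply(sc, parts$train$X)
    Xte <- standardizer_apply(sc, parts$test$X)
    tpr_of <- function(fit) {
      classification_report(confusion(parts$test$y,
                                      predict(fit, Xte)$labels))$tpr
    }
    c(w = tpr_of(welm_fit(Xtr, parts$train$y, seed = s)),
      u = tpr_of(elm_fit(Xtr, parts$train$y, seed = s)))
  }, c(w = 0, u = 0))
  expect_gte(median(tpr_pair["w", ] - tpr_pair["u", ]), 0)
})

test_that("multilayer fit separates Gaussian blobs and is seed-stable", {
  ds <- skewed_separable(20, 40, sep = 4, d = 4, seed = 71)
  m <- pgmelm_fit(ds$X, ds$y, P = 10, Q = 2, seed = 5)
  pr <- predict(m, ds$X)
  rep <- classification_report(confusion(ds$y, pr$labels))
  expect_gte(rep$g_mean, 0.95)

  # seeded determinism of the full parameter set
  m2 <- pgmelm_fit(ds$X, ds$y, P = 10, Q = 2, seed = 5)
  expect_identical(m$beta, m2$beta)
  expect_identical(m$feature_layers[[1]]$beta, m2$feature_layers[[1]]$beta)

  # structure contract: Q feature layers + decision layer
  expect_length(m$feature_layers, 2)
  expect_identical(length(m$feature_layers) + 1L, m$Q + 1L)
  expect_error(pgmelm_fit(ds$X, ds$y, P = 0, Q = 1), class = "pgmelm_structure_error")
})

test_that("prediction thresholds scores at one half and stays finite", {
  ds <- skewed_separable(15, 30, d = 3, seed = 81)
  m <- elm_fit(ds$X, ds$y, seed = 2)
  pr <- predict(m, ds$X)
  expect_identical(pr$labels, as.integer(pr$scores >= 0.5))
  expect_true(all(is.finite(predict(m, matrix(0, 1, 3))$scores)))
  expect_error(predict(m, matrix(0, 2, 5)), class = "pgmelm_shape_error")

  # separable training data is classified correctly
  expect_identical(pr$labels, ds$y)
})

test_that("a near-balanced pipeline degenerates to one autoencoder plus ELM", {
  ds <- make_imbalanced(30, 40, seed = 91)      # floor(40/30) = 1: no GAN
  fit <- pgmelm(ds, seed = 17)
  expect_identical(fit$balanced$num, 1L)
  expect_identical(fit$structure$Q, 1L)
  expect_equal(fit$balanced$delta_ir, 0)
  expect_identical(sum(fit$balanced$generated_mask), 0L)

  # identical to the manually composed single ELM-AE + ELM on the same PCs
  Z <- pca_transform(fit$pca, standardizer_apply(fit$scaler, ds$X))
  seed_fit <- pgmelm:::derive_seed(17L, 202L)
  ae <- elm_ae_fit(Z, fit$structure$P, seed = pgmelm:::derive_seed(seed_fit, 1L))
  expect_identical(fit$model$feature_layers[[1]]$beta, ae$beta)
})

test_that("models round-trip through serialization bit-exactly", {
  ds <- skewed_separable(12, 36, d = 4, seed = 101)
  fit <- pgmelm(imb_dataset(ds$X, ds$y), config = quick_gan(), seed = 7)
  path <- tempfile(fileext = ".rds")
  model_save(fit, path)
  back <- model_load(path)
  Xnew <- matrix(rnorm(40), 10, 4)
  expect_identical(predict(fit, Xnew), predict(back, Xnew))
  unlink(path)
})
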