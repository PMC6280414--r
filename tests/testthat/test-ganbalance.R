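test_that("the GAN repetition count and ratio change follow the floor rule", {
  expect_identical(num_gan_runs(26, 224), 8L)
  expect_identical(num_gan_runs(100, 300), 3L)
  expect_identical(num_gan_runs(100, 100), 1L)
  expect_error(num_gan_runs(0, 10), class = "pgmelm_empty_minority")

  expect_equal(delta_ir(26, 224), 0.8125)
  expect_equal(delta_ir(212, 357), 0)
  for (n in c(1, 7, 30)) expect_equal(delta_ir(n, n), 0)
})

test_that("ratio change lies in [0, 1) and balancing never overshoots", {
  for (n_min in 1:50) {
    for (n_maj in n_min:50) {
      d <- delta_ir(n_min, n_maj)
      expect_gte(d, 0)
      expect_lt(d, 1)
      ir <- n_min / n_maj
      ir_prime <- num_gan_runs(n_min, n_maj) * n_min / n_maj
      expect_lte(ir_prime, 1)
      expect_gte(ir_prime, ir)
    }
  }
})

test_that("GAN training is reproducible and records a convergence trace", {
  X <- gaussian2d(40, seed = 5)
  cfg <- quick_gan(epochs = 40)
  a <- train_dynamic_gan(X, cfg, seed = 11)
  b <- train_dynamic_gan(X, cfg, seed = 11)
  expect_identical(a$theta_g, b$theta_g)
  expect_identical(a$theta_d, b$theta_d)
  expect_identical(a$trace, b$trace)
  expect_identical(nrow(a$trace), 40L)
  expect_true(all(is.finite(a$trace$d_loss)))
  expect_true(all(a$trace$mean_d > 0 & a$trace$mean_d < 1))
  expect_error(train_dynamic_gan(X[1, , drop = FALSE]),
               class = "pgmelm_insufficient_data")
})

test_that("sampling from a trained generator honours count, range and seed", {
  X <- gaussian2d(40, seed = 6)
  gan <- train_dynamic_gan(X, quick_gan(epochs = 30), seed = 3)

  empty <- generate_minority(gan, 0)
  expect_identical(dim(empty), c(0L, 2L))

  s1 <- generate_minority(gan, 25, seed = 4)
  s2 <- generate_minority(gan, 25, seed = 4)
  expect_identical(s1, s2)
  expect_identical(dim(s1), c(25L, 2L))
  expect_true(all(is.finite(s1)))
  # sigmoid output mapped back to the min-max box of the training chunk
  expect_true(all(sweep(s1, 2, apply(X, 2, max)) <= 1e-9))
  expect_true(all(sweep(s1, 2, apply(X, 2, min)) >= -1e-9))

  expect_error(generate_minority(list(), 5), class = "pgmelm_state_error")
})

test_that("generated samples match the training moments", {
  X <- gaussian2d(200, seed = 42)
  gan <- train_dynamic_gan(X, gan_config(), seed = 1)
  gen <- generate_minority(gan, 200, seed = 2)
  se <- apply(X, 2, sd) / sqrt(nrow(X))
  expect_true(all(abs(colMeans(gen) - colMeans(X)) < 3 * se))
})

test_that("training moves the generator towards the data distribution", {
  X <- gaussian2d(120, seed = 8)
  held <- gaussian2d(120, seed = 9)
  deltas <- vapply(1:3, function(s) {
    early <- train_dynamic_gan(X, quick_gan(epochs = 1), seed = s)
    late <- train_dynamic_gan(X, quick_gan(epochs = 250), seed = s)
    kernel_mmd(generate_minority(late, 120, seed = s + 50), held) -
      kernel_mmd(generate_minority(early, 120, seed = s + 50), held)
  }, 0)
  expect_lt(median(deltas), 0)
})

test_that("GAN balancing reaches the prescribed counts without touching the majority", {
  ds <- make_imbalanced(10, 43, n_informative = 2, n_redundant = 0,
                        n_noise = 0, seed = 15)
  bal <- balance_dataset(ds, quick_gan(epochs = 50), seed = 2)
  expect_identical(bal$num, 4L)
  expect_identical(bal$n_prime, 4L * 10L + 43L)
  expect_identical(sum(bal$generated_mask), 3L * 10L)
  expect_identical(sum(bal$y == 1L), 4L * 10L)
  expect_equal(bal$delta_ir, delta_ir(10, 43))
  expect_equal(bal$ir_prime, num_gan_runs(10, 43) * 10 / 43)

  # majority rows pass through bit-identically
  expect_identical(bal$X[bal$y == 0L & !bal$generated_mask, ],
                   ds$X[ds$y == 0L, ])
  # original minority rows retained
  expect_identical(bal$X[bal$y == 1L & !bal$generated_mask, ],
                   ds$X[ds$y == 1L, ])
})

test_that("a near-balanced dataset passes through the balancer unchanged", {
  ds <- make_imbalanced(30, 40, seed = 16)  # floor = 1
  bal <- balance_dataset(ds, quick_gan())
  expect_identical(bal$num, 1L)
  expect_identical(bal$X, ds$X)
  expect_identical(bal$y, ds$y)
  expect_equal(bal$delta_ir, 0)
  expect_null(bal$gan)
})

test_that("liver-scale counts produce the expected balanced size", {
  ds <- make_imbalanced(26, 224, n_informative = 2, n_redundant = 0,
                        n_noise = 0, seed = 17)
  bal <- balance_dataset(ds, quick_gan(epochs = 30), seed = 3)
  expect_identical(bal$num, 8L)
  expect_identical(bal$n_prime, 432L)
  expect_identical(sum(bal$generated_mask), 182L)
})

test_that("SMOTE interpolates inside minority neighbourhoods", {
  # degenerate geometry: identical minority points reproduce that point
  Xmin <- matrix(1, 6, 2)
  Xmaj <- matrix(rnorm(60), 30) + 5
  ds <- imb_dataset(rbind(Xmin, Xmaj), rep(c(1L, 0L), c(6, 30)))
  bal <- smote_oversample(ds, k = 2, target_count = 10, seed = 1)
  expect_true(all(bal$X[bal$generated_mask, ] == 1))
  expect_identical(sum(bal$generated_mask), 10L)

  # two minority points, k = 1: synthetics lie on the connecting segment
  A <- c(0, 0); B <- c(2, 4)
  ds2 <- imb_dataset(rbind(A, B, matrix(rnorm(40) + 8, 20)),
                     rep(c(1L, 0L), c(2, 20)))
  bal2 <- smote_oversample(ds2, k = 1, target_count = 30, seed = 2)
  syn <- bal2$X[bal2$generated_mask, ]
  t_par <- syn[, 1] / 2
  expect_true(all(t_par >= 0 & t_par <= 1))
  expect_equal(syn[, 2], 4 * t_par, tolerance = 1e-12)

  expect_error(smote_oversample(ds2, k = 2), class = "pgmelm_neighbourhood_error")
})
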