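test_that("L1 and MSE agree with brute-force pixel loops and their identities", {
  set.seed(101)
  a <- matrix(runif(64 * 64), 64, 64)
  b <- matrix(runif(64 * 64), 64, 64)
  expect_equal(loss_l1(a, b), oracle_mean_abs(a, b))
  expect_equal(image_mse(a, b), oracle_mean_sq(a, b))
  expect_identical(loss_l1(a, a), 0)
  expect_equal(loss_l1(matrix(0, 64, 64), matrix(1, 64, 64)), 1)
  expect_equal(image_mse(a, a + 0.1), 0.01, tolerance = 1e-12)
  expect_equal(loss_l1(a, b), loss_l1(b, a))
  expect_error(loss_l1(a, matrix(0, 32, 32)), "shape")
})

test_that("SSIM satisfies its bounds and matches a from-definition single-window value", {
  set.seed(102)
  a <- matrix(runif(64 * 64), 64, 64)
  b <- matrix(runif(64 * 64), 64, 64)
  expect_equal(image_ssim(a, a), 1)
  expect_equal(loss_ssim(a, a), 0)
  ls <- loss_ssim(a, b)
  expect_gte(ls, 0); expect_lte(ls, 2)
  # constant-plus-gradient pair: every window sees identical statistics up to
  # the window weighting, so compare against near-constant fields where the
  # windowed and single-window definitions coincide
  g1 <- matrix(0.4, 30, 30)
  g2 <- matrix(0.6, 30, 30)
  expect_equal(1 - loss_ssim(g1, g2), oracle_ssim_single(g1, g2),
               tolerance = 1e-10)
})

test_that("SSIM loss gradient matches central finite differences", {
  set.seed(103)
  a <- matrix(runif(64 * 64), 64, 64)
  b <- matrix(runif(64 * 64), 64, 64)
  g <- nodulegp:::ssim_loss_grad(a, b)
  eps <- 1e-5
  idx <- cbind(c(2, 17, 40, 63), c(5, 33, 12, 60))
  for (r in seq_len(nrow(idx))) {
    ap <- a; am <- a
    ap[idx[r, 1], idx[r, 2]] <- ap[idx[r, 1], idx[r, 2]] + eps
    am[idx[r, 1], idx[r, 2]] <- am[idx[r, 1], idx[r, 2]] - eps
    fd <- (loss_ssim(ap, b) - loss_ssim(am, b)) / (2 * eps)
    expect_equal(g[idx[r, 1], idx[r, 2]], fd, tolerance = 1e-5)
  }
})

test_that("perceptual loss is a non-negative distance, zero on identical inputs,
           and reduces to mean squared difference under the identity extractor", {
  set.seed(104)
  a <- matrix(runif(64 * 64), 64, 64)
  b <- matrix(runif(64 * 64), 64, 64)
  fx <- perceptual_extractor(seed = 5, base = 4)
  expect_equal(loss_perceptual(a, a, fx), 0, tolerance = 1e-12)
  expect_gte(loss_perceptual(a, b, fx), 0)
  expect_equal(loss_perceptual(a, b, identity_extractor()),
               oracle_mean_sq(a, b), tolerance = 1e-12)
})

test_that("adversarial loss is the negated mean critic score", {
  expect_equal(loss_adversarial(c(0, 0)), 0)
  expect_equal(loss_adversarial(c(1, 3)), -2)
  set.seed(105)
  for (i in 1:5) {
    s <- rnorm(sample(2:20, 1))
    expect_equal(loss_adversarial(s), -sum(s) / length(s))
  }
  expect_error(loss_adversarial(numeric(0)), "empty")
})

test_that("the composite generative loss recomposes from its terms and is linear in each weight", {
  set.seed(106)
  a <- matrix(runif(64 * 64), 64, 64)
  b <- matrix(runif(64 * 64), 64, 64)
  scores <- rnorm(4)
  fx <- perceptual_extractor(seed = 5, base = 4)
  zero <- generative_loss(a, b, scores, loss_weights(0, 0, 0, 0, 0), fx)
  expect_equal(zero$total, 0)
  only_l1 <- generative_loss(a, b, scores, loss_weights(1, 0, 0, 0, 0), fx)
  expect_equal(only_l1$total, loss_l1(a, b))
  w <- loss_weights(2.5, 1.5, 0.7, 0.3)
  full <- generative_loss(a, b, scores, w, fx)
  manual <- 2.5 * loss_l1(a, b) + 1.5 * loss_ssim(a, b) +
    0.7 * loss_perceptual(a, b, fx) + 0.3 * loss_adversarial(scores)
  expect_equal(full$total, manual)
  expect_length(full$terms, 4)
  # linearity in lambda2
  w2 <- loss_weights(2.5, 3.0, 0.7, 0.3)
  expect_equal(generative_loss(a, b, scores, w2, fx)$total - full$total,
               1.5 * loss_ssim(a, b), tolerance = 1e-10)
  expect_error(loss_weights(-1, 0, 0, 0), "non-negative")
})
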