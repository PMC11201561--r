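test_that("predictor preserves shape, bounds and is deterministic under fixed weights", {
  m <- predictor_new(depth = 2, base = 4, seed = 3)
  p <- render_patch(sample_nodule_params(2, "malignant"), 0)
  out1 <- predictor_forward(m, p)
  out2 <- predictor_forward(m, p)
  expect_identical(dim(out1), c(64L, 64L))
  expect_true(all(out1 >= 0 & out1 <= 1))
  expect_identical(unclass(out1), unclass(out2))
  expect_error(predictor_forward(m, matrix(0.5, 32, 32)), "64x64")
  # same seed, fresh model: identical outputs (stable initialization)
  m2 <- predictor_new(depth = 2, base = 4, seed = 3)
  expect_identical(unclass(predictor_forward(m2, p)), unclass(out1))
})

test_that("critic returns one finite unbounded score and batches equal single calls", {
  cr <- critic_new(base = 2, seed = 5)
  patches <- lapply(1:4, function(i)
    render_patch(sample_nodule_params(i, "benign"), 0))
  singles <- vapply(patches, function(p) discriminator_forward(cr, p),
                    numeric(1))
  expect_true(all(is.finite(singles)))
  batch <- discriminator_forward_batch(cr, patches)
  expect_equal(batch, singles, tolerance = 1e-10)
  # zero critic scores everything 0
  cz <- cr
  for (i in 1:5) {
    cz$params$convs[[i]]$W[] <- 0
    cz$params$convs[[i]]$b[] <- 0
  }
  cz$params$v[] <- 0; cz$params$c <- 0
  expect_identical(discriminator_forward(cz, patches[[1]]), 0)
  expect_error(discriminator_forward(cr, matrix(0, 8, 8)), "shape")
})

test_that("gradient penalty matches closed forms for constant and affine critics", {
  real <- lapply(1:3, function(i) render_patch(sample_nodule_params(i, "benign"), 0))
  gen <- lapply(4:6, function(i) render_patch(sample_nodule_params(i, "benign"), 0))
  # constant critic: gradient norm 0 everywhere, penalty (0 - 1)^2 = 1
  cz <- critic_new(base = 2, seed = 1)
  for (i in 1:5) {
    cz$params$convs[[i]]$W[] <- 0
    cz$params$convs[[i]]$b[] <- 0
  }
  cz$params$v[] <- 0; cz$params$c <- 7
  expect_equal(as.numeric(gradient_penalty(cz, real, gen, c(0.2, 0.5, 0.9))), 1)
  dl <- discriminator_loss(cz, real, gen, loss_weights(lambdaD = 10),
                           t_samples = c(0.2, 0.5, 0.9))
  expect_equal(dl$total, 10)   # Wasserstein terms cancel, penalty = 1
  # affine critic (positive biases keep every activation in the linear
  # region): gradient is a constant w; penalty = (||w|| - 1)^2 independent of
  # the interpolation point, with ||w|| obtained by exhaustive finite
  # differences of the score
  ca <- critic_new(base = 1, seed = 6, size = 32)
  for (i in 1:5) {
    ca$params$convs[[i]]$W <- ca$params$convs[[i]]$W * 0.3
    ca$params$convs[[i]]$b[] <- 5
  }
  x0 <- matrix(runif(32 * 32, 0.3, 0.7), 32, 32)
  s0 <- discriminator_forward(ca, x0)
  eps <- 1e-4
  w_fd <- matrix(0, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    xp <- x0; xp[i, j] <- xp[i, j] + eps
    w_fd[i, j] <- (discriminator_forward(ca, xp) - s0) / eps
  }
  expected <- (sqrt(sum(w_fd^2)) - 1)^2
  r32 <- lapply(1:2, function(i) image_patch(matrix(runif(1024, 0.3, 0.7), 32, 32)))
  g32 <- lapply(1:2, function(i) image_patch(matrix(runif(1024, 0.3, 0.7), 32, 32)))
  pen <- gradient_penalty(ca, r32, g32, c(0.3, 0.8))
  expect_equal(as.numeric(pen), expected, tolerance = 1e-4)
  expect_equal(attr(pen, "gnorm")[1], attr(pen, "gnorm")[2], tolerance = 1e-8)
  expect_error(gradient_penalty(ca, r32, g32, c(0.3, 1.2)), "0, 1")
})

test_that("interpolation endpoints recover the real and generated images exactly", {
  xr <- array(runif(16 * 16 * 2), c(16, 16, 2, 1))
  xg <- array(runif(16 * 16 * 2), c(16, 16, 2, 1))
  x1 <- nodulegp:::interpolate_batch(xr, xg, c(1, 1))
  x0 <- nodulegp:::interpolate_batch(xr, xg, c(0, 0))
  expect_identical(x1, xr)
  expect_identical(x0, xg)
})

test_that("discriminator loss follows the printed sign convention and its gradients
           match finite differences", {
  real <- lapply(1:2, function(i) render_patch(sample_nodule_params(i, "benign"), 0))
  gen <- lapply(3:4, function(i) render_patch(sample_nodule_params(i, "benign"), 0))
  # hand-set scores via a zero critic with adjustable bias: D() = c
  # printed convention: LD = -E D(GX) + E D(XF); with lambdaD = 0 and
  # constant scores 1 and 2 the total is -1 + 2 = 1
  cz <- critic_new(base = 2, seed = 2)
  for (i in 1:5) { cz$params$convs[[i]]$W[] <- 0; cz$params$convs[[i]]$b[] <- 0 }
  cz$params$v[] <- 0
  # score both batches with biases 1 (generated) and 2 (real) by scoring twice
  cz$params$c <- 1
  s_gen <- discriminator_forward_batch(cz, gen)
  cz$params$c <- 2
  s_real <- discriminator_forward_batch(cz, real)
  expect_equal(-mean(s_gen) + mean(s_real), 1)
  # full parameter gradient of the trained loss against finite differences
  cr <- critic_new(base = 2, seed = 8)
  xg <- nodulegp:::as_tensor(gen)
  xr <- nodulegp:::as_tensor(real)
  ts <- c(0.4, 0.7)
  lambdaD <- 3
  loss_of <- function(cr) {
    s_g <- nodulegp:::critic_fwd(cr, xg)$score
    s_r <- nodulegp:::critic_fwd(cr, xr)$score
    xhat <- nodulegp:::interpolate_batch(xr, xg, ts)
    gp <- nodulegp:::critic_gp_grads(cr, xhat)
    (mean(s_g) - mean(s_r)) + lambdaD * gp$penalty
  }
  fwd_g <- nodulegp:::critic_fwd(cr, xg, keep_cache = TRUE)
  fwd_r <- nodulegp:::critic_fwd(cr, xr, keep_cache = TRUE)
  gr <- nodulegp:::add_grads(
    nodulegp:::add_grads(
      nodulegp:::critic_bwd_params(cr, fwd_g, rep(1 / 2, 2)),
      nodulegp:::critic_bwd_params(cr, fwd_r, rep(-1 / 2, 2))),
    nodulegp:::scale_grads(
      nodulegp:::critic_gp_grads(cr, nodulegp:::interpolate_batch(xr, xg, ts))$grads,
      lambdaD))
  eps <- 1e-5
  probes <- list(c(1, 1), c(2, 3), c(5, 2))
  for (pr in probes) {
    li <- pr[1]; wi <- pr[2]
    crp <- cr; crm <- cr
    crp$params$convs[[li]]$W[wi, 1] <- crp$params$convs[[li]]$W[wi, 1] + eps
    crm$params$convs[[li]]$W[wi, 1] <- crm$params$convs[[li]]$W[wi, 1] - eps
    fd <- (loss_of(crp) - loss_of(crm)) / (2 * eps)
    expect_equal(gr$convs[[li]]$W[wi, 1], fd, tolerance = 1e-4)
  }
})

test_that("training honors the critic/generator schedule and zero iterations keep init", {
  ds <- micro_dataset()
  cfg0 <- micro_train_config(iterations = 0)
  st0 <- train(ds, cfg0)
  init <- predictor_new(cfg0$predictor_depth, cfg0$predictor_base,
                        seed = derive_seed(cfg0$seed, 10L))
  expect_identical(st0$predictor$params, init$params)
  expect_equal(st0$iteration, 0)

  cfg <- micro_train_config(iterations = 3, n_critic = 2)
  st <- train(ds, cfg)
  expect_identical(nrow(st$history), 3L)
  expect_true(all(is.finite(st$history$l1)))
  expect_identical(st$critic_updates, 6L)   # n_critic updates per generator step
  expect_error(train(structure(list(), class = "nodule_dataset"), cfg), "empty")
})

test_that("training is reproducible and checkpoints round-trip", {
  ds <- micro_dataset()
  cfg <- micro_train_config(iterations = 2)
  st1 <- train(ds, cfg)
  st2 <- train(ds, cfg)
  expect_identical(st1$predictor$params, st2$predictor$params)
  expect_identical(st1$history, st2$history)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(st1, f)
  back <- load_checkpoint(f)
  expect_identical(back$predictor$params, st1$predictor$params)
  unlink(f)
})

test_that("deployment requires an explicit freeze and batch equals per-item prediction", {
  ds <- micro_dataset(2, 2, seed = 6)
  st <- train(ds, micro_train_config(iterations = 1))
  expect_error(predict_followup(st$predictor, list(ds[[1]]$baseline)),
               "frozen")
  frozen <- freeze_predictor(st$predictor)
  baselines <- lapply(ds, `[[`, "baseline")
  batch <- predict_followup(frozen, baselines)
  expect_length(batch, 4)
  singles <- lapply(baselines, function(b) predictor_forward(frozen, b))
  for (i in seq_along(batch))
    expect_equal(unclass(batch[[i]]), unclass(singles[[i]]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  # repeat call identical
  again <- predict_followup(frozen, baselines)
  expect_identical(batch, again)
})
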