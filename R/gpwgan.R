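# The adversarial growth predictor: an encoder-decoder predictor network with
# skip connections maps a baseline nodule patch to its predicted follow-up
# appearance; a five-convolution Wasserstein critic scores patches with an
# unbounded scalar. The critic loss carries a gradient penalty on images
# interpolated between real follow-ups and predictions; its parameter
# gradient requires differentiating through the critic's own input gradient,
# implemented below with a forward-over-reverse (tangent) pass. All layers of
# the critic are piecewise linear, so the a.e. derivative of the activation
# masks is zero and the tangent pass is exact almost everywhere.

#' Create a growth-predictor network
#'
#' Encoder-decoder with skip connections ("modified U-Net"): each encoder
#' level is conv 3x3 + instance norm + leaky ReLU followed by 2x mean
#' pooling; the decoder mirrors it with nearest-neighbour upsampling, skip
#' concatenation, conv + instance norm + ReLU. The head is residual: a final
#' 3x3 conv predicts the change from baseline to follow-up, which is added to
#' the input and clamped to `[0, 1]` (a bounded output that is the identity
#' map at initialization -- the network learns the growth delta, not the
#' whole image). Input and output are 64 x 64 single-channel patches.
#'
#' @param depth Number of encoder levels (default 4).
#' @param base Channel count of the first level, doubled per level
#'   (default 32).
#' @param seed Seed for weight initialization.
#' @param size Input patch side (must be divisible by `2^depth`).
#' @return A `predictor_model`.
#' @export
predictor_new <- function(depth = 4, base = 32, seed = 1, size = 64) {
  stopifnot(size %% 2^depth == 0)
  ch <- base * 2^(0:(depth - 1))
  bott_ch <- base * 2^depth
  params <- with_local_seed(seed, {
    enc <- lapply(seq_len(depth), function(i) {
      cin <- if (i == 1) 1 else ch[i - 1]
      list(conv = conv_init(3, cin, ch[i]), norm = instnorm_init(ch[i]))
    })
    bott <- list(conv = conv_init(3, ch[depth], bott_ch),
                 norm = instnorm_init(bott_ch))
    dec <- lapply(seq_len(depth), function(i) {
      cin <- (if (i == depth) bott_ch else ch[i + 1]) + ch[i]
      list(conv = conv_init(3, cin, ch[i]), norm = instnorm_init(ch[i]))
    })
    out <- list(conv = conv_init(3, ch[1], 1, gain = 0.3))
    list(enc = enc, bott = bott, dec = dec, out = out)
  })
  structure(list(params = params, depth = depth, base = base, size = size,
                 seed = seed, frozen = FALSE),
            class = "predictor_model")
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf("<predictor_model: depth %d, base %d channels, %dx%d patches%s>\n",
              x$depth, x$base, x$size, x$size,
              if (x$frozen) ", frozen" else ""))
  invisible(x)
}

# full forward pass on a (H, W, N, 1) tensor; cache retained for backprop
predictor_fwd <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  d <- model$depth
  cache <- list(enc = vector("list", d), dec = vector("list", d))
  h <- x
  skips <- vector("list", d)
  for (i in seq_len(d)) {
    cv <- conv_fwd(h, p$enc[[i]]$conv)
    nm <- instnorm_fwd(cv$out, p$enc[[i]]$norm)
    ac <- lrelu_fwd(nm$out)
    skips[[i]] <- ac$out
    if (keep_cache) cache$enc[[i]] <- list(cv = cv, nm = nm, mask = ac$mask)
    h <- pool_fwd(ac$out)
  }
  cvb <- conv_fwd(h, p$bott$conv)
  nmb <- instnorm_fwd(cvb$out, p$bott$norm)
  acb <- lrelu_fwd(nmb$out)
  if (keep_cache) cache$bott <- list(cv = cvb, nm = nmb, mask = acb$mask,
                                     din = dim(h))
  h <- acb$out
  for (i in rev(seq_len(d))) {
    up <- up_fwd(h)
    cat_in <- cat_channels(up, skips[[i]])
    cv <- conv_fwd(cat_in, p$dec[[i]]$conv)
    nm <- instnorm_fwd(cv$out, p$dec[[i]]$norm)
    ac <- relu_fwd(nm$out)
    if (keep_cache) cache$dec[[i]] <- list(cv = cv, nm = nm, mask = ac$mask,
                                           c_up = dim(up)[4])
    h <- ac$out
  }
  cvo <- conv_fwd(h, p$out$conv)
  raw <- x + cvo$out                      # residual head
  out <- pmin(pmax(raw, 0), 1)
  if (keep_cache)
    cache$out <- list(cv = cvo, clip_mask = (raw > 0 & raw < 1) * 1)
  list(out = array(out, dim(x)), cache = if (keep_cache) cache else NULL)
}

# backprop dL/d(output) to parameter gradients (input gradient not needed)
predictor_bwd <- function(model, cache, dout) {
  p <- model$params
  d <- model$depth
  grads <- list(enc = vector("list", d), dec = vector("list", d))
  g <- dout * cache$out$clip_mask
  grads$out <- list(conv = conv_bwd_params(g, cache$out$cv$P))
  g <- conv_bwd_input(g, p$out$conv, cache$out$cv$din)
  skip_grads <- vector("list", d)
  for (i in seq_len(d)) {  # decoder blocks, shallowest first
    cc <- cache$dec[[i]]
    g <- g * cc$mask
    nb <- instnorm_bwd(g, p$dec[[i]]$norm, cc$nm)
    grads$dec[[i]] <- list(conv = conv_bwd_params(nb$dx, cc$cv$P),
                           norm = list(g = nb$g, b = nb$b))
    g <- conv_bwd_input(nb$dx, p$dec[[i]]$conv, cc$cv$din)
    sp <- split_channels(g, cc$c_up)
    skip_grads[[i]] <- sp[[2]]
    g <- up_bwd(sp[[1]])   # continues to the next-deeper decoder block
  }
  cc <- cache$bott
  g <- g * cc$mask
  nb <- instnorm_bwd(g, p$bott$norm, cc$nm)
  grads$bott <- list(conv = conv_bwd_params(nb$dx, cc$cv$P),
                     norm = list(g = nb$g, b = nb$b))
  g <- conv_bwd_input(nb$dx, p$bott$conv, cc$cv$din)
  for (i in rev(seq_len(d))) {  # encoder blocks, deepest first
    g <- pool_bwd(g) + skip_grads[[i]]
    cc <- cache$enc[[i]]
    g <- g * cc$mask
    nb <- instnorm_bwd(g, p$enc[[i]]$norm, cc$nm)
    grads$enc[[i]] <- list(conv = conv_bwd_params(nb$dx, cc$cv$P),
                           norm = list(g = nb$g, b = nb$b))
    g <- conv_bwd_input(nb$dx, p$enc[[i]]$conv, cc$cv$din)
  }
  grads
}

#' Run the predictor on one patch
#'
#' Deterministic given fixed weights; shape-preserving (64 x 64 in, 64 x 64
#' out) with values in `[0, 1]` from the bounded output activation.
#'
#' @param model A `predictor_model`.
#' @param baseline An [image_patch()] (or matrix) matching the model size.
#' @return An [image_patch()] of the predicted follow-up appearance.
#' @export
predictor_forward <- function(model, baseline) {
  m <- as_mat(baseline)
  if (nrow(m) != model$size || ncol(m) != model$size)
    stop(sprintf("predictor_forward: expected %dx%d input", model$size, model$size))
  x <- array(m, c(model$size, model$size, 1, 1))
  out <- predictor_fwd(model, x)$out
  image_patch(pmin(pmax(out[, , 1, 1], 0), 1),
              if (is_image_patch(baseline)) patch_spacing(baseline) else 0.5)
}

#' Freeze a predictor for deployment
#'
#' After training, only the predictor is kept and its weights are immutable;
#' [predict_followup()] refuses unfrozen models so the freeze step is
#' explicit.
#'
#' @param model A `predictor_model`.
#' @return The model with `frozen = TRUE`.
#' @export
freeze_predictor <- function(model) {
  model$frozen <- TRUE
  model
}

#' Predict follow-up patches for a set of baselines
#'
#' @param model A frozen `predictor_model`.
#' @param baselines List of [image_patch()]s.
#' @param batch_size Internal batch size.
#' @return List of predicted follow-up patches ("GP-nodules"), one per input.
#' @export
predict_followup <- function(model, baselines, batch_size = 16) {
  if (!isTRUE(model$frozen))
    stop("predict_followup: model must be frozen first (freeze_predictor)")
  n <- length(baselines)
  out <- vector("list", n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1)
    x <- as_tensor(baselines[idx])
    y <- predictor_fwd(model, x)$out
    for (j in seq_along(idx))
      out[[idx[j]]] <- image_patch(pmin(pmax(y[, , j, 1], 0), 1),
                                   patch_spacing(baselines[[idx[j]]]))
  }
  out
}

# ---- critic ----------------------------------------------------------------

#' Create a Wasserstein critic network
#'
#' Five 3x3 convolution layers (leaky ReLU, 2x mean pooling after each, no
#' normalization layers -- normalization across the batch interacts badly
#' with the per-sample gradient penalty), followed by global average pooling
#' and a linear head producing one unbounded real score per patch.
#'
#' @param base First-layer width, doubled per layer (default 32, giving
#'   widths 32..512).
#' @param seed Seed for weight initialization.
#' @param size Input patch side (must be divisible by 32).
#' @return A `critic_model`.
#' @export
critic_new <- function(base = 32, seed = 2, size = 64) {
  stopifnot(size %% 32 == 0)
  widths <- base * 2^(0:4)
  params <- with_local_seed(seed, {
    convs <- lapply(1:5, function(i)
      conv_init(3, if (i == 1) 1 else widths[i - 1], widths[i]))
    list(convs = convs,
         v = rnorm(widths[5], 0, 1 / sqrt(widths[5])),
         c = 0)
  })
  structure(list(params = params, widths = widths, seed = seed, size = size),
            class = "critic_model")
}

#' @export
print.critic_model <- function(x, ...) {
  cat(sprintf("<critic_model: 5 conv layers, widths %s>\n",
              paste(x$widths, collapse = "-")))
  invisible(x)
}

critic_fwd <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  h <- x
  cache <- vector("list", 5)
  for (i in 1:5) {
    cv <- conv_fwd(h, p$convs[[i]])
    ac <- lrelu_fwd(cv$out)
    if (keep_cache) cache[[i]] <- list(P = cv$P, din = cv$din, mask = ac$mask,
                                       dconv = dim(cv$out))
    h <- pool_fwd(ac$out)
  }
  d <- dim(h)
  feat <- matrix(colMeans(matrix(h, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  score <- as.numeric(feat %*% p$v + p$c)
  list(score = score, feat = feat, dtop = d,
       cache = if (keep_cache) cache else NULL)
}

# gradient of sum(ds * score) wrt the critic input
critic_bwd_input <- function(model, fwd, ds) {
  p <- model$params
  d <- fwd$dtop
  hw <- d[1] * d[2]
  dfeat <- outer(ds, p$v)                      # N x C
  g <- array(rep(as.numeric(dfeat) / hw, each = hw), d)
  for (i in 5:1) {
    g <- pool_bwd(g)
    g <- g * fwd$cache[[i]]$mask
    g <- conv_bwd_input(g, p$convs[[i]], fwd$cache[[i]]$din)
  }
  g
}

# gradients of sum(ds * score) wrt critic parameters
critic_bwd_params <- function(model, fwd, ds) {
  p <- model$params
  d <- fwd$dtop
  hw <- d[1] * d[2]
  grads <- list(convs = vector("list", 5),
                v = as.numeric(crossprod(fwd$feat, ds)),
                c = sum(ds))
  dfeat <- outer(ds, p$v)
  g <- array(rep(as.numeric(dfeat) / hw, each = hw), d)
  for (i in 5:1) {
    g <- pool_bwd(g)
    g <- g * fwd$cache[[i]]$mask
    grads$convs[[i]] <- conv_bwd_params(g, fwd$cache[[i]]$P)
    if (i > 1) g <- conv_bwd_input(g, p$convs[[i]], fwd$cache[[i]]$din)
  }
  grads
}

#' Critic score for one patch
#'
#' @param model A `critic_model`.
#' @param patch An [image_patch()] or matrix of the model's input size.
#' @return One finite real (no squashing: Wasserstein critic contract).
#' @export
discriminator_forward <- function(model, patch) {
  m <- as_mat(patch)
  if (nrow(m) != model$size || ncol(m) != model$size)
    stop("discriminator_forward: input shape mismatch")
  critic_fwd(model, array(m, c(model$size, model$size, 1, 1)))$score
}

#' Critic scores for a list of patches
#' @param model A `critic_model`.
#' @param patches List of patches.
#' @return Numeric vector of scores, one per patch.
#' @export
discriminator_forward_batch <- function(model, patches) {
  critic_fwd(model, as_tensor(patches))$score
}

# ---- gradient penalty -------------------------------------------------------

# per-sample gradient norms of the critic at x, plus everything the tangent
# (double-backprop) pass needs
critic_input_grads <- function(model, x) {
  fwd <- critic_fwd(model, x, keep_cache = TRUE)
  g <- critic_bwd_input(model, fwd, rep(1, dim(x)[3]))
  gm <- apply(g, 3, function(s) sqrt(sum(s^2)))
  list(fwd = fwd, g = g, gnorm = gm)
}

#' Gradient penalty of a critic on interpolated patches
#'
#' For each pair, forms `xhat = t * real + (1 - t) * generated`, computes the
#' critic's gradient with respect to `xhat`, and returns the mean of
#' `(||grad||_2 - 1)^2` (unscaled; the `lambdaD` scaling is applied in
#' [discriminator_loss()]).
#'
#' @param critic A `critic_model`.
#' @param real_batch,generated_batch Lists of patches of equal length.
#' @param t_samples Numeric vector in `[0, 1]`, one per pair.
#' @return The mean penalty, with attribute `gnorm` (per-pair gradient norms).
#' @export
gradient_penalty <- function(critic, real_batch, generated_batch, t_samples) {
  if (length(real_batch) != length(generated_batch) ||
      length(t_samples) != length(real_batch))
    stop("gradient_penalty: batch/t length mismatch")
  if (any(t_samples < 0 | t_samples > 1))
    stop("gradient_penalty: t_samples must lie in [0, 1]")
  xr <- as_tensor(real_batch)
  xg <- as_tensor(generated_batch)
  xhat <- interpolate_batch(xr, xg, t_samples)
  ig <- critic_input_grads(critic, xhat)
  structure(mean((ig$gnorm - 1)^2), gnorm = ig$gnorm)
}

interpolate_batch <- function(xr, xg, t) {
  xhat <- xg
  for (i in seq_along(t))
    xhat[, , i, ] <- t[i] * xr[, , i, ] + (1 - t[i]) * xg[, , i, ]
  xhat
}

# parameter gradients of mean over samples of (||grad_x D||_2 - 1)^2 at xhat.
# Forward-over-reverse: with u = grad_x D(xhat) held fixed,
# d/dtheta ||g||^2 = 2 d/dtheta (g . u) and (g . u) is the directional
# derivative of D along u, computed by a tangent pass through the (piecewise
# linear) critic; its theta-gradient is a standard reverse pass over the
# tangent graph. Biases receive no penalty gradient (their tangent is zero).
critic_gp_grads <- function(model, xhat) {
  p <- model$params
  n <- dim(xhat)[3]
  ig <- critic_input_grads(model, xhat)
  gnorm <- ig$gnorm
  penalty <- mean((gnorm - 1)^2)

  # tangent forward along u = g, reusing the primal masks
  tang <- vector("list", 5)
  th <- ig$g
  for (i in 1:5) {
    d <- dim(th)
    P <- im2col_cpp(th, d[1], d[2], d[3], d[4], 3L, 1L)
    z <- array(P %*% p$convs[[i]]$W, c(d[1], d[2], d[3], p$convs[[i]]$cout))
    z <- z * ig$fwd$cache[[i]]$mask
    tang[[i]] <- list(P = P, din = d)
    th <- pool_fwd(z)
  }
  d <- dim(th)
  hw <- d[1] * d[2]
  tfeat <- matrix(colMeans(matrix(th, hw, d[3] * d[4])), d[3], d[4])
  # sanity quantity: tfeat %*% v equals ||g||^2 per sample (a.e.)

  # reverse pass over the tangent graph with per-sample chain coefficient
  coef <- ifelse(gnorm > 1e-12, 2 * (gnorm - 1) / gnorm, 0) / n
  grads <- list(convs = vector("list", 5),
                v = as.numeric(crossprod(tfeat, coef)),
                c = 0)
  dfeat <- outer(coef, p$v)
  g <- array(rep(as.numeric(dfeat) / hw, each = hw), d)
  for (i in 5:1) {
    g <- pool_bwd(g)
    g <- g * ig$fwd$cache[[i]]$mask
    grads$convs[[i]] <- list(W = crossprod(tang[[i]]$P,
                                           matrix(g, prod(dim(g)[1:3]), dim(g)[4])),
                             b = numeric(p$convs[[i]]$cout))
    if (i > 1) g <- conv_bwd_input(g, p$convs[[i]], tang[[i]]$din)
  }
  list(penalty = penalty, gnorm = gnorm, grads = grads)
}

#' Critic (discriminator) loss with gradient penalty
#'
#' Two sign conventions are exposed. `"printed"` is
#' `LD = -E[D(GX)] + E[D(XF)] + lambdaD * GP`, the form some WGAN papers
#' print; `"standard"` is its mirror `LD = E[D(GX)] - E[D(XF)] + lambdaD * GP`
#' (the critic, minimizing LD, then scores real follow-ups above
#' predictions). Training uses `"standard"`, which produces the adversarial
#' game the generator's `-E[D(GX)]` objective expects; see the methods
#' vignette.
#'
#' @param critic A `critic_model`.
#' @param real_batch,generated_batch Lists of patches of equal length.
#' @param weights A [loss_weights()] (only `lambdaD` is used).
#' @param t_samples Interpolation coefficients in `[0, 1]`, one per pair.
#' @param sign_convention `"printed"` or `"standard"`.
#' @return List with `total` and `terms` (`wasserstein`, `penalty`).
#' @export
discriminator_loss <- function(critic, real_batch, generated_batch,
                               weights = loss_weights(), t_samples,
                               sign_convention = c("printed", "standard")) {
  sign_convention <- match.arg(sign_convention)
  s_gen <- discriminator_forward_batch(critic, generated_batch)
  s_real <- discriminator_forward_batch(critic, real_batch)
  w <- -mean(s_gen) + mean(s_real)
  if (sign_convention == "standard") w <- -w
  gp <- as.numeric(gradient_penalty(critic, real_batch, generated_batch, t_samples))
  list(total = w + weights$lambdaD * gp,
       terms = c(wasserstein = w, penalty = gp))
}

# ---- training ---------------------------------------------------------------

#' Training configuration for the adversarial growth predictor
#'
#' @param weights A [loss_weights()].
#' @param iterations Number of generator update steps.
#' @param n_critic Critic updates per generator update (default 5, the usual
#'   gradient-penalty recipe).
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param betas Adam momentum parameters.
#' @param seed Master seed; init, batch order and interpolation draws use
#'   independent derived streams.
#' @param predictor_depth,predictor_base,critic_base Architecture sizes.
#' @param sign_convention Critic loss convention used for training updates.
#' @param extractor_seed Seed of the fixed perceptual extractor.
#' @return A `train_config` list.
#' @export
train_config <- function(weights = loss_weights(), iterations = 200,
                         n_critic = 5, batch_size = 8, lr = 1e-4,
                         betas = c(0, 0.9), seed = 1,
                         predictor_depth = 4, predictor_base = 32,
                         critic_base = 32,
                         sign_convention = "standard",
                         extractor_seed = 77, extractor_base = 16) {
  cfg <- as.list(environment())
  class(cfg) <- "train_config"
  cfg
}

#' Train the growth predictor adversarially
#'
#' Alternating updates: `n_critic` critic steps (Wasserstein loss with
#' gradient penalty) per generator step (composite synthesis loss). All
#' randomness comes from streams derived from `config$seed`.
#'
#' @param dataset A `nodule_dataset` (non-empty).
#' @param config A [train_config()].
#' @return A `training_state`: `predictor`, `critic`, `history` (one row per
#'   generator step with all loss terms), `config`, `iteration`.
#' @export
train <- function(dataset, config = train_config()) {
  if (length(dataset) == 0) stop("train: empty dataset")
  n <- length(dataset)
  X <- as_tensor(lapply(dataset, `[[`, "baseline"))
  XF <- as_tensor(lapply(dataset, `[[`, "followup"))

  predictor <- predictor_new(config$predictor_depth, config$predictor_base,
                             seed = derive_seed(config$seed, 10L))
  critic <- critic_new(config$critic_base,
                       seed = derive_seed(config$seed, 11L))
  fx <- perceptual_extractor(seed = config$extractor_seed,
                             base = config$extractor_base)
  opt_g <- adam_new(predictor$params, lr = config$lr,
                    beta1 = config$betas[1], beta2 = config$betas[2])
  opt_d <- adam_new(critic$params, lr = config$lr,
                    beta1 = config$betas[1], beta2 = config$betas[2])
  w <- config$weights
  d_sign <- if (config$sign_convention == "standard") 1 else -1
  bs <- min(config$batch_size, n)
  K <- ssim_kernel(predictor$size)

  hist <- vector("list", config$iterations)
  batch_seed <- derive_seed(config$seed, 12L)
  t_seed <- derive_seed(config$seed, 13L)
  step <- 0L
  critic_updates <- 0L
  state <- with_local_seed(batch_seed, {
    # epoch-based cyclic batching: each pair is visited once per epoch in a
    # reshuffled order, which keeps the minibatch composition comparable
    # across training and lowers the variance of the recorded loss terms
    queue <- integer(0)
    next_batch <- function() {
      while (length(queue) < bs) queue <<- c(queue, sample.int(n))
      idx <- queue[seq_len(bs)]
      queue <<- queue[-seq_len(bs)]
      idx
    }
    for (step in seq_len(config$iterations)) {
      d_terms <- c(wasserstein = NA_real_, penalty = NA_real_)
      for (j in seq_len(config$n_critic)) {
        idx <- next_batch()
        xb <- X[, , idx, , drop = FALSE]
        xfb <- XF[, , idx, , drop = FALSE]
        gx <- predictor_fwd(predictor, xb)$out
        ts <- with_local_seed(derive_seed(t_seed, step * 1000L + j), runif(bs))
        xhat <- interpolate_batch(xfb, gx, ts)

        fwd_g <- critic_fwd(critic, gx, keep_cache = TRUE)
        fwd_r <- critic_fwd(critic, xfb, keep_cache = TRUE)
        # d(total)/dscore under the chosen sign convention
        gr_g <- critic_bwd_params(critic, fwd_g, rep(d_sign / bs, bs))
        gr_r <- critic_bwd_params(critic, fwd_r, rep(-d_sign / bs, bs))
        gp <- critic_gp_grads(critic, xhat)
        grads <- add_grads(add_grads(gr_g, gr_r),
                           scale_grads(gp$grads, w$lambdaD))
        if (!all(is.finite(c(fwd_g$score, fwd_r$score, gp$penalty))))
          stop("train: non-finite critic loss at step ", step)
        st <- adam_step(critic$params, grads, opt_d)
        critic$params <- st$params; opt_d <- st$opt
        critic_updates <- critic_updates + 1L
        d_terms <- c(wasserstein = d_sign * (mean(fwd_r$score) - mean(fwd_g$score)),
                     penalty = gp$penalty)
      }

      idx <- next_batch()
      xb <- X[, , idx, , drop = FALSE]
      xfb <- XF[, , idx, , drop = FALSE]
      fw <- predictor_fwd(predictor, xb, keep_cache = TRUE)
      gx <- fw$out

      # per-term values and d(loss)/d(gx)
      diff <- gx - xfb
      l1 <- mean(abs(diff))
      d_l1 <- sign(diff) / length(diff)
      ssim_v <- 0; d_ssim <- array(0, dim(gx))
      for (s in seq_len(bs)) {
        a <- gx[, , s, 1]; b2 <- xfb[, , s, 1]
        ssim_v <- ssim_v + (1 - mean(ssim_stats(a, b2, K = K)$S)) / bs
        d_ssim[, , s, 1] <- ssim_loss_grad(a, b2, K = K) / bs
      }
      lp <- perceptual_loss_grad(gx, xfb, fx)
      fwd_gc <- critic_fwd(critic, gx, keep_cache = TRUE)
      adv <- -mean(fwd_gc$score)
      d_adv <- critic_bwd_input(critic, fwd_gc, rep(-1 / bs, bs))

      dgx <- w$lambda1 * d_l1 + w$lambda2 * d_ssim +
        w$lambda3 * lp$grad + w$lambda4 * d_adv
      g_grads <- predictor_bwd(predictor, fw$cache, dgx)
      if (!all(is.finite(c(l1, ssim_v, lp$value, adv))))
        stop("train: non-finite generator loss at step ", step)
      st <- adam_step(predictor$params, g_grads, opt_g)
      predictor$params <- st$params; opt_g <- st$opt

      hist[[step]] <- data.frame(
        step = step, l1 = l1, ssim = ssim_v, lp = lp$value, adv = adv,
        total = w$lambda1 * l1 + w$lambda2 * ssim_v + w$lambda3 * lp$value +
          w$lambda4 * adv,
        d_wasserstein = d_terms[["wasserstein"]],
        d_penalty = d_terms[["penalty"]])
    }
    list(predictor = predictor, critic = critic)
  })
  structure(list(predictor = state$predictor, critic = state$critic,
                 history = do.call(rbind, hist), config = config,
                 iteration = config$iterations,
                 critic_updates = critic_updates),
            class = "training_state")
}

#' @export
print.training_state <- function(x, ...) {
  cat(sprintf("<training_state: %d generator steps>\n", x$iteration))
  if (x$iteration > 0) {
    h <- x$history
    cat(sprintf("  final losses: L1 %.4f, 1-SSIM %.4f, LP %.5f, adv %.3f\n",
                h$l1[nrow(h)], h$ssim[nrow(h)], h$lp[nrow(h)], h$adv[nrow(h)]))
  }
  invisible(x)
}

add_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- add_grads(a[[nm]], b[[nm]])
    a
  } else a + b
}

scale_grads <- function(a, s) {
  if (is.list(a)) lapply(a, scale_grads, s = s) else a * s
}

#' Save / load a model checkpoint
#'
#' Self-describing archive: architecture descriptors, weights, loss weights,
#' seeds and the R version that wrote it.
#'
#' @param state A `training_state` (or a list with `predictor`/`critic`).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(state, path) {
  meta <- list(r_version = as.character(getRversion()),
               package_version = as.character(utils::packageVersion("nodulegp")))
  saveRDS(list(state = state, meta = meta), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)$state
}
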