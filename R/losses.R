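#' Loss weights for the adversarial synthesis objective
#'
#' The generator objective is
#' `LG = lambda1 * L1 + lambda2 * LSSIM + lambda3 * LLP + lambda4 * LA`
#' and the critic carries a gradient penalty weighted by `lambdaD`. Defaults
#' follow the common L1-dominant image-translation weighting and the standard
#' gradient-penalty weight 10.
#'
#' @param lambda1,lambda2,lambda3,lambda4 Non-negative weights of the L1,
#'   structural-similarity, learned-perceptual and adversarial terms.
#' @param lambdaD Non-negative gradient-penalty weight.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda1 = 100, lambda2 = 10, lambda3 = 1,
                         lambda4 = 1, lambdaD = 10) {
  w <- list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
            lambda4 = lambda4, lambdaD = lambdaD)
  if (!all(vapply(w, function(x) is.finite(x) && x >= 0, logical(1))))
    stop("loss_weights: all weights must be finite and non-negative")
  class(w) <- "loss_weights"
  w
}

as_mat <- function(x) {
  m <- as.matrix(x)
  attributes(m) <- list(dim = dim(m))
  m
}

check_same_shape <- function(a, b) {
  if (!identical(dim(as.matrix(a)), dim(as.matrix(b))))
    stop("inputs must have identical shapes")
}

#' Mean absolute pixel difference
#' @param generated,target Patches (matrices or [image_patch()]s) of equal shape.
#' @return Scalar `>= 0`; 0 iff the inputs are identical.
#' @export
loss_l1 <- function(generated, target) {
  check_same_shape(generated, target)
  mean(abs(as_mat(generated) - as_mat(target)))
}

#' Mean squared pixel difference
#' @inheritParams loss_l1
#' @return Scalar `>= 0`.
#' @export
image_mse <- function(generated, target) {
  check_same_shape(generated, target)
  mean((as_mat(generated) - as_mat(target))^2)
}

# ---- SSIM -----------------------------------------------------------------

ssim_kernel <- function(n, win = 11, sigma = 1.5) {
  g <- exp(-0.5 * ((seq_len(win) - (win + 1) / 2) / sigma)^2)
  g <- g / sum(g)
  m <- n - win + 1
  K <- matrix(0, m, n)
  for (i in seq_len(m)) K[i, i:(i + win - 1)] <- g
  K
}

ssim_stats <- function(a, b, C1 = 1e-4, C2 = 9e-4, K = NULL) {
  n <- nrow(a)
  if (is.null(K)) K <- ssim_kernel(n)
  f <- function(x) K %*% x %*% t(K)
  mua <- f(a); mub <- f(b)
  saa <- f(a * a) - mua^2
  sbb <- f(b * b) - mub^2
  sab <- f(a * b) - mua * mub
  A1 <- 2 * mua * mub + C1
  A2 <- 2 * sab + C2
  B1 <- mua^2 + mub^2 + C1
  B2 <- saa + sbb + C2
  list(S = (A1 * A2) / (B1 * B2), mua = mua, mub = mub,
       A1 = A1, A2 = A2, B1 = B1, B2 = B2, K = K)
}

#' Structural similarity index between two patches
#'
#' Windowed SSIM with the reference defaults: 11 x 11 Gaussian window
#' (`sigma = 1.5`), stability constants `K1 = 0.01`, `K2 = 0.03`, dynamic
#' range 1 (valid windows only, no padding). Returns the mean over windows,
#' a value in `[-1, 1]` with `image_ssim(a, a) = 1`.
#'
#' @inheritParams loss_l1
#' @return Mean SSIM.
#' @export
image_ssim <- function(generated, target) {
  check_same_shape(generated, target)
  mean(ssim_stats(as_mat(generated), as_mat(target))$S)
}

#' Structural dissimilarity loss `1 - SSIM`
#' @inheritParams loss_l1
#' @return Scalar in `[0, 2]`; 0 for identical inputs.
#' @export
loss_ssim <- function(generated, target) {
  1 - image_ssim(generated, target)
}

# gradient of loss_ssim wrt the generated patch (single pair)
ssim_loss_grad <- function(a, b, K = NULL) {
  st <- ssim_stats(a, b, K = K)
  S <- st$S
  P <- length(S)
  Dmu <- 2 * st$mub * st$A2 / (st$B1 * st$B2) - S * 2 * st$mua / st$B1
  Dsx <- -S / st$B2
  Dsxy <- 2 * st$A1 / (st$B1 * st$B2)
  Kt <- t(st$K)
  adj <- function(F) Kt %*% F %*% st$K
  dmean <- (adj(Dmu) + 2 * a * adj(Dsx) - 2 * adj(st$mua * Dsx) +
              b * adj(Dsxy) - adj(st$mub * Dsxy)) / P
  -dmean   # loss = 1 - mean(S)
}

# ---- perceptual loss ------------------------------------------------------

#' Build a fixed perceptual feature extractor
#'
#' A small two-stage convolutional feature extractor in the spirit of the
#' early residual stages of an image classifier: features are tapped at the
#' end of each stage, unit-normalized across channels, and compared with a
#' squared distance. Weights are randomly initialized from `seed` and then
#' fixed; random deep features are a serviceable perceptual metric when no
#' pretrained weights are available, and the seed is recorded so runs are
#' reproducible.
#'
#' @param seed Integer seed for the fixed weights.
#' @param base Channel width of the first stage (second stage doubles it).
#' @return A `feature_extractor` object for [loss_perceptual()].
#' @export
perceptual_extractor <- function(seed = 77, base = 16) {
  layers <- with_local_seed(seed, list(
    c1 = conv_init(3, 1, base),
    c2 = conv_init(3, base, base),
    c3 = conv_init(3, base, 2 * base),
    c4 = conv_init(3, 2 * base, 2 * base)))
  structure(list(type = "conv", layers = layers, normalize = TRUE, seed = seed),
            class = "feature_extractor")
}

#' An identity feature extractor (features = raw pixels)
#'
#' Useful as a degenerate extractor: with it, [loss_perceptual()] reduces to
#' the mean squared pixel difference.
#' @return A `feature_extractor`.
#' @export
identity_extractor <- function() {
  structure(list(type = "identity", normalize = FALSE),
            class = "feature_extractor")
}

# forward through the extractor; x is a (H, W, N, 1) tensor
extractor_fwd <- function(fx, x) {
  if (fx$type == "identity")
    return(list(taps = list(x), cache = NULL))
  L <- fx$layers
  c1 <- conv_fwd(x, L$c1);  r1 <- relu_fwd(c1$out)
  c2 <- conv_fwd(r1$out, L$c2); r2 <- relu_fwd(c2$out)   # tap 1
  p  <- pool_fwd(r2$out)
  c3 <- conv_fwd(p, L$c3);  r3 <- relu_fwd(c3$out)
  c4 <- conv_fwd(r3$out, L$c4); r4 <- relu_fwd(c4$out)   # tap 2
  list(taps = list(r2$out, r4$out),
       cache = list(r1 = r1, r2 = r2, r3 = r3, r4 = r4,
                    dp = dim(p), din = dim(x)))
}

# backprop tap gradients to the extractor input
extractor_bwd <- function(fx, cache, dtaps) {
  if (fx$type == "identity") return(dtaps[[1]])
  L <- fx$layers
  g <- dtaps[[2]] * cache$r4$mask
  g <- conv_bwd_input(g, L$c4, dim(cache$r3$out))
  g <- g * cache$r3$mask
  g <- conv_bwd_input(g, L$c3, cache$dp)  # c3 input was the pooled activation
  g <- pool_bwd(g)
  g <- g + dtaps[[1]]
  g <- g * cache$r2$mask
  g <- conv_bwd_input(g, L$c2, dim(cache$r1$out))
  g <- g * cache$r1$mask
  conv_bwd_input(g, L$c1, cache$din)
}

chan_normalize <- function(f, eps = 1e-8) {
  d <- dim(f)
  m <- matrix(f, prod(d[1:3]), d[4])
  nrm <- sqrt(rowSums(m^2) + eps)
  list(y = array(m / nrm, d), nrm = nrm)
}

chan_normalize_bwd <- function(dy, y, nrm) {
  d <- dim(y)
  my <- matrix(y, prod(d[1:3]), d[4])
  mdy <- matrix(dy, prod(d[1:3]), d[4])
  dot <- rowSums(mdy * my)
  array((mdy - my * dot) / nrm, d)
}

# batched perceptual loss with gradient wrt `gen`
perceptual_loss_grad <- function(gen, target, fx, want_grad = TRUE) {
  fg <- extractor_fwd(fx, gen)
  ft <- extractor_fwd(fx, target)
  total <- 0
  dtaps <- vector("list", length(fg$taps))
  norms <- vector("list", length(fg$taps))
  for (i in seq_along(fg$taps)) {
    a <- fg$taps[[i]]; b <- ft$taps[[i]]
    if (isTRUE(fx$normalize)) {
      na <- chan_normalize(a); nb <- chan_normalize(b)
      diff <- na$y - nb$y
      total <- total + mean(diff^2)
      if (want_grad) {
        dya <- 2 * diff / length(diff)
        dtaps[[i]] <- chan_normalize_bwd(dya, na$y, na$nrm)
      }
    } else {
      diff <- a - b
      total <- total + mean(diff^2)
      if (want_grad) dtaps[[i]] <- 2 * diff / length(diff)
    }
  }
  grad <- if (want_grad) extractor_bwd(fx, fg$cache, dtaps) else NULL
  list(value = total, grad = grad)
}

#' Learned perceptual loss between two patches
#'
#' Mean squared distance between channel-normalized feature maps of the two
#' patches, summed over the extractor's tap layers. Zero for identical
#' inputs, always `>= 0`.
#'
#' @inheritParams loss_l1
#' @param feature_extractor A [perceptual_extractor()] or
#'   [identity_extractor()].
#' @return Scalar `>= 0`.
#' @export
loss_perceptual <- function(generated, target,
                            feature_extractor = perceptual_extractor()) {
  check_same_shape(generated, target)
  g <- as_mat(generated); t2 <- as_mat(target)
  xg <- array(g, c(nrow(g), ncol(g), 1, 1))
  xt <- array(t2, c(nrow(g), ncol(g), 1, 1))
  perceptual_loss_grad(xg, xt, feature_extractor, want_grad = FALSE)$value
}

#' Adversarial (Wasserstein generator) loss
#'
#' The generator maximizes the critic's score on its outputs, i.e. minimizes
#' `-mean(scores)`.
#'
#' @param critic_scores_on_generated Non-empty numeric vector of critic scores.
#' @return `-mean(scores)`.
#' @export
loss_adversarial <- function(critic_scores_on_generated) {
  if (length(critic_scores_on_generated) == 0)
    stop("loss_adversarial: empty score vector")
  -mean(critic_scores_on_generated)
}

#' Composite generative loss
#'
#' `LG = lambda1 * L1 + lambda2 * LSSIM + lambda3 * LLP + lambda4 * LA`, with
#' the four unweighted terms returned alongside the total.
#'
#' @inheritParams loss_l1
#' @param critic_scores Critic scores on the generated patch(es).
#' @param weights A [loss_weights()].
#' @param feature_extractor Extractor for the perceptual term.
#' @return List with `total` and `terms` (named numeric vector
#'   `l1, ssim, lp, adv`).
#' @export
generative_loss <- function(generated, target, critic_scores,
                            weights = loss_weights(),
                            feature_extractor = perceptual_extractor()) {
  terms <- c(l1 = loss_l1(generated, target),
             ssim = loss_ssim(generated, target),
             lp = loss_perceptual(generated, target, feature_extractor),
             adv = loss_adversarial(critic_scores))
  total <- weights$lambda1 * terms[["l1"]] + weights$lambda2 * terms[["ssim"]] +
    weights$lambda3 * terms[["lp"]] + weights$lambda4 * terms[["adv"]]
  list(total = total, terms = terms)
}
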