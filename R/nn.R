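# Minimal reverse-mode convolutional network engine.
#
# Tensors are numeric arrays with dim (H, W, N, C). Convolutions are lowered
# to one BLAS matmul via im2col (src/convops.cpp); every forward helper
# returns the quantities its backward needs. This engine exists because the
# adversarial growth predictor is the package's own model: its gradients
# (including the critic's double backprop for the gradient penalty) are
# derived and implemented here, not delegated.

as_tensor <- function(patches) {
  # list of image_patch -> (H, W, N, 1) tensor
  n <- length(patches)
  h <- nrow(patches[[1]])
  x <- array(0, c(h, h, n, 1))
  for (i in seq_len(n)) x[, , i, 1] <- patch_values(patches[[i]])
  x
}

tensor_to_patches <- function(x, spacing = 0.5) {
  lapply(seq_len(dim(x)[3]), function(i)
    image_patch(pmin(pmax(x[, , i, 1], 0), 1), spacing))
}

conv_init <- function(k, cin, cout, gain = 1) {
  sd <- gain * sqrt(2 / (k * k * cin))
  list(W = matrix(rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout),
       b = numeric(cout), k = k, cin = cin, cout = cout)
}

conv_fwd <- function(x, layer) {
  d <- dim(x)
  P <- im2col_cpp(x, d[1], d[2], d[3], d[4], layer$k, (layer$k - 1L) %/% 2L)
  out <- P %*% layer$W
  out <- sweep_bias(out, layer$b)
  list(out = array(out, c(d[1], d[2], d[3], layer$cout)), P = P, din = d)
}

sweep_bias <- function(m, b) {
  if (all(b == 0)) return(m)
  m + rep(b, each = nrow(m))
}

# gradient wrt the conv input
conv_bwd_input <- function(dout, layer, din) {
  d <- dim(dout)
  dP <- matrix(dout, prod(d[1:3]), d[4]) %*% t(layer$W)
  col2im_cpp(dP, din[1], din[2], din[3], din[4], layer$k, (layer$k - 1L) %/% 2L)
}

# gradients wrt the conv parameters (P cached from the forward pass)
conv_bwd_params <- function(dout, P) {
  d <- dim(dout)
  dm <- matrix(dout, prod(d[1:3]), d[4])
  list(W = crossprod(P, dm), b = colSums(dm))
}

lrelu_fwd <- function(x, alpha = 0.2) {
  mask <- alpha + (1 - alpha) * (x > 0)
  list(out = x * mask, mask = mask)
}

relu_fwd <- function(x) {
  mask <- (x > 0) * 1
  list(out = x * mask, mask = mask)
}

sigmoid_fwd <- function(x) {
  out <- 1 / (1 + exp(-x))
  list(out = out, grad = out * (1 - out))
}

pool_fwd <- function(x) {
  d <- dim(x)
  avgpool2_cpp(x, d[1], d[2], d[3], d[4])
}

pool_bwd <- function(g) {
  d <- dim(g)
  avgpool2_back_cpp(g, d[1], d[2], d[3], d[4])
}

up_fwd <- function(x) {
  d <- dim(x)
  upsample2_cpp(x, d[1], d[2], d[3], d[4])
}

up_bwd <- function(g) {
  d <- dim(g)
  upsample2_back_cpp(g, d[1], d[2], d[3], d[4])
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3], da[4] + db[4]))
}

split_channels <- function(g, c1) {
  d <- dim(g)
  n1 <- prod(d[1:3]) * c1
  list(array(g[seq_len(n1)], c(d[1], d[2], d[3], c1)),
       array(g[(n1 + 1):length(g)], c(d[1], d[2], d[3], d[4] - c1)))
}

# instance normalization: standardize each (sample, channel) plane, then a
# learned per-channel affine map
instnorm_init <- function(cout) list(g = rep(1, cout), b = numeric(cout))

instnorm_fwd <- function(x, layer, eps = 1e-5) {
  d <- dim(x)
  hw <- d[1] * d[2]
  m <- matrix(x, hw, d[3] * d[4])
  mu <- colMeans(m)
  va <- colMeans(m^2) - mu^2
  inv <- 1 / sqrt(va + eps)
  xhat <- (m - rep(mu, each = hw)) * rep(inv, each = hw)
  gfull <- rep(layer$g, each = d[3])     # per (sample, channel) column
  bfull <- rep(layer$b, each = d[3])
  out <- xhat * rep(gfull, each = hw) + rep(bfull, each = hw)
  list(out = array(out, d), xhat = xhat, inv = inv, d = d)
}

instnorm_bwd <- function(dout, layer, cache) {
  d <- cache$d
  hw <- d[1] * d[2]
  dm <- matrix(dout, hw, d[3] * d[4])
  gfull <- rep(layer$g, each = d[3])
  dxhat <- dm * rep(gfull, each = hw)
  # per-column standardization backward
  s1 <- colMeans(dxhat)
  s2 <- colMeans(dxhat * cache$xhat)
  dx <- (dxhat - rep(s1, each = hw) - cache$xhat * rep(s2, each = hw)) *
    rep(cache$inv, each = hw)
  # columns are ordered sample-fastest within channel: fold samples out
  dg_col <- colSums(dm * cache$xhat)
  db_col <- colSums(dm)
  list(dx = array(dx, d),
       g = colSums(matrix(dg_col, d[3], d[4])),
       b = colSums(matrix(db_col, d[3], d[4])))
}

# ---- Adam ----------------------------------------------------------------

adam_new <- function(params, lr = 1e-4, beta1 = 0, beta2 = 0.9, eps = 1e-8) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like)
    else if (is.numeric(x)) x * 0
    else x
  }
  list(m = zero_like(params), v = zero_like(params), t = 0,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(params, grads, opt) {
  opt$t <- opt$t + 1
  t <- opt$t; b1 <- opt$beta1; b2 <- opt$beta2
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else if (is.numeric(p) && is.numeric(g)) {
      m2 <- b1 * m + (1 - b1) * g
      v2 <- b2 * v + (1 - b2) * g^2
      mhat <- m2 / (1 - b1^t)
      vhat <- v2 / (1 - b2^t)
      list(p = p - opt$lr * mhat / (sqrt(vhat) + opt$eps), m = m2, v = v2)
    } else list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, opt$m, opt$v)
  opt$m <- r$m; opt$v <- r$v
  list(params = r$p, opt = opt)
}
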