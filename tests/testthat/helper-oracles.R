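# Independent oracles used across tests. These deliberately re-derive each
# quantity from its definition by brute force, sharing no code with the
# package implementation they check.

# Equivalent-area diameter from a half-level threshold mask: background from
# the patch border, box-blur denoise, count pixels above half level.
oracle_diameter <- function(patch) {
  v <- unclass(patch); attributes(v) <- list(dim = dim(v))
  n <- nrow(v)
  # 3x3 box blur, edge-replicated
  pad <- matrix(0, n + 2, n + 2)
  pad[2:(n + 1), 2:(n + 1)] <- v
  pad[1, ] <- pad[2, ]; pad[n + 2, ] <- pad[n + 1, ]
  pad[, 1] <- pad[, 2]; pad[, n + 2] <- pad[, n + 1]
  sm <- matrix(0, n, n)
  for (a in 0:2) for (b in 0:2)
    sm <- sm + pad[(1 + a):(n + a), (1 + b):(n + b)] / 9
  bg <- median(c(sm[1, ], sm[n, ], sm[, 1], sm[, n]))
  half <- bg + (max(sm) - bg) / 2
  area_px <- sum(sm > half)
  2 * sqrt(area_px / pi) * attr(patch, "pixel_spacing_mm")
}

# all-pairs Mann-Whitney AUC with the 1/2 tie convention
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# rank-based AUC (identical value to oracle_auc, O(n log n)); used where the
# all-pairs loop would be too slow (bootstrap replicates)
oracle_auc_fast <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Hochberg step-up adjustment straight from the definition
oracle_hochberg <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min((m - seq(i, m) + 1) * ps[seq(i, m)]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force mean absolute / squared differences via explicit loops
oracle_mean_abs <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    tot <- tot + abs(a[i, j] - b[i, j])
  tot / (nrow(a) * ncol(a))
}

oracle_mean_sq <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    tot <- tot + (a[i, j] - b[i, j])^2
  tot / (nrow(a) * ncol(a))
}

# single-window SSIM from the definition (uniform window over the full
# matrix), for checking the windowed implementation on a constant-plus-
# gradient pair where every Gaussian window sees the same statistics
oracle_ssim_single <- function(a, b, C1 = 1e-4, C2 = 9e-4) {
  mua <- mean(a); mub <- mean(b)
  va <- mean(a^2) - mua^2; vb <- mean(b^2) - mub^2
  cab <- mean(a * b) - mua * mub
  ((2 * mua * mub + C1) * (2 * cab + C2)) /
    ((mua^2 + mub^2 + C1) * (va + vb + C2))
}

# small deterministic micro-config for fast training tests
micro_train_config <- function(iterations = 2, seed = 11, n_critic = 2) {
  train_config(iterations = iterations, n_critic = n_critic, batch_size = 4,
               lr = 1e-3, betas = c(0.5, 0.9), seed = seed,
               predictor_depth = 2, predictor_base = 4, critic_base = 2,
               extractor_base = 4)
}

micro_dataset <- function(n_mal = 3, n_ben = 5, seed = 4) {
  generate_dataset(n_mal, n_ben, seed = seed)
}

# shared state for expensive fixtures built once per test run
.fixture_env <- new.env(parent = emptyenv())
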