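#' Derive a child seed from a master seed
#'
#' Splitmix-style 32-bit integer hash used everywhere the package needs
#' independent reproducible random streams (one per simulated subject, one per
#' pipeline stage). Mixing the index through multiply-xor-shift rounds avoids
#' the correlated streams that `master_seed + index` would produce.
#'
#' @param master_seed Non-negative integer master seed.
#' @param index Non-negative integer stream index (subject number, stage id...).
#' @return A single integer in `[0, 2^31 - 1]`, a valid `set.seed()` argument.
#' @export
derive_seed <- function(master_seed, index) {
  stopifnot(length(master_seed) == 1L, length(index) == 1L,
            master_seed >= 0, index >= 0)
  # 32-bit arithmetic emulated in doubles (exact below 2^53)
  z <- (master_seed %% 2^32 + mul32(0x9E3779B9, (index + 1) %% 2^32)) %% 2^32
  mix <- function(z, mult, shift) {
    z <- bitwXor64(z, floor(z / 2^shift))
    mul32(z, mult)
  }
  z <- mix(z, 0x85EBCA6B, 16)
  z <- mix(z, 0xC2B2AE35, 13)
  z <- bitwXor64(z, floor(z / 2^16))
  as.integer(z %% 2^31)
}

# 32-bit modular multiply in exact double arithmetic (16-bit limb split)
mul32 <- function(a, b) {
  hi_a <- floor(a / 2^16); lo_a <- a %% 2^16
  hi_b <- floor(b / 2^16); lo_b <- b %% 2^16
  cross <- (lo_a * hi_b + hi_a * lo_b) %% 2^16
  (lo_a * lo_b + cross * 2^16) %% 2^32
}

# xor of two non-negative doubles interpreted as 32-bit integers
bitwXor64 <- function(a, b) {
  hi_a <- floor(a / 2^16); lo_a <- a %% 2^16
  hi_b <- floor(b / 2^16); lo_b <- b %% 2^16
  bitwXor(as.integer(hi_a), as.integer(hi_b)) * 2^16 +
    bitwXor(as.integer(lo_a), as.integer(lo_b))
}

#' Hash an R object to a short hex string
#'
#' FNV-1a over the object's canonical JSON serialization; used to stamp
#' experiment artifacts with a configuration fingerprint.
#'
#' @param x An R object (must be JSON-serializable).
#' @return An 8-hex-digit string.
#' @export
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b)
    h <- mul32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}
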