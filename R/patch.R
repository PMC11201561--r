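#' Nodule image patch
#'
#' A 64 x 64 matrix of intensities in `[0, 1]` representing a
#' 32 mm x 32 mm axial CT region of interest at 0.5 mm/pixel, the unit image
#' of the whole package (simulator output, network input/output, similarity
#' metrics).
#'
#' @param values Numeric 64 x 64 matrix (or any square matrix) with finite
#'   values in `[0, 1]`.
#' @param pixel_spacing_mm Pixel spacing in millimetres (default 0.5).
#' @return An `image_patch` object: the matrix with `pixel_spacing_mm` and
#'   `side_mm` attributes.
#' @export
image_patch <- function(values, pixel_spacing_mm = 0.5) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), pixel_spacing_mm > 0)
  if (!all(is.finite(values)))
    stop("image_patch: all values must be finite")
  if (any(values < 0 | values > 1))
    stop("image_patch: values must lie in [0, 1]")
  structure(values,
            pixel_spacing_mm = pixel_spacing_mm,
            side_mm = ncol(values) * pixel_spacing_mm,
            class = c("image_patch", "matrix", "array"))
}

#' @export
print.image_patch <- function(x, ...) {
  cat(sprintf("<image_patch %dx%d, %.2f mm/px, side %.1f mm, range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), attr(x, "pixel_spacing_mm"), attr(x, "side_mm"),
              min(x), max(x)))
  invisible(x)
}

is_image_patch <- function(x) inherits(x, "image_patch")

patch_spacing <- function(x) attr(x, "pixel_spacing_mm")

# strip attributes for numeric work
patch_values <- function(x) {
  v <- unclass(x)
  attributes(v) <- list(dim = dim(v))
  v
}

#' Measure the apparent diameter of a nodule in a patch
#'
#' Full-width-at-half-maximum estimate: the background level is taken as the
#' median of the patch border, the peak as the maximum of a lightly smoothed
#' patch; radial rays are cast from the peak and the half-level crossing is
#' located on each ray with linear sub-pixel interpolation. The median over
#' rays makes the estimate robust to spiculations and noise.
#'
#' @param patch An [image_patch()].
#' @param n_angles Number of rays (default 32).
#' @return Diameter in millimetres.
#' @export
measure_diameter <- function(patch, n_angles = 32) {
  sp <- patch_spacing(patch)
  v <- smooth_3x3(patch_values(patch))
  n <- nrow(v)
  border <- c(v[1, ], v[n, ], v[, 1], v[, n])
  bg <- median(border)
  peak <- max(v)
  half <- bg + 0.5 * (peak - bg)
  # ray origin: centroid of the above-half mask (argmax wanders on the flat
  # plateau of large solid nodules)
  mask <- v > half
  pk_idx <- if (any(mask)) {
    w <- which(mask, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  } else {
    as.numeric(which(v == peak, arr.ind = TRUE)[1, ])
  }
  angles <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  rmax <- n / 2 - 1
  rs <- seq(0, rmax, by = 0.25)
  radii <- vapply(angles, function(a) {
    xi <- pk_idx[1] + rs * cos(a)
    yi <- pk_idx[2] + rs * sin(a)
    ok <- xi >= 1 & xi <= n & yi >= 1 & yi <= n
    prof <- bilinear_at(v, xi[ok], yi[ok])
    below <- which(prof < half)
    if (length(below) == 0) return(NA_real_)
    b <- below[1]
    if (b == 1) return(0)
    # linear interpolation between the last sample above and first below
    r1 <- rs[ok][b - 1]; r2 <- rs[ok][b]
    p1 <- prof[b - 1]; p2 <- prof[b]
    r1 + (p1 - half) / (p1 - p2) * (r2 - r1)
  }, numeric(1))
  radii <- radii[is.finite(radii)]
  if (length(radii) == 0) return(0)
  2 * median(radii) * sp
}

bilinear_at <- function(m, x, y) {
  n <- nrow(m)
  x0 <- pmax(1, pmin(n - 1, floor(x))); y0 <- pmax(1, pmin(n - 1, floor(y)))
  fx <- x - x0; fy <- y - y0
  m[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    m[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    m[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    m[cbind(x0 + 1, y0 + 1)] * fx * fy
}

smooth_3x3 <- function(m) {
  n <- nrow(m)
  p <- matrix(0, n + 2, n + 2)
  p[2:(n + 1), 2:(n + 1)] <- m
  p[1, ] <- p[2, ]; p[n + 2, ] <- p[n + 1, ]
  p[, 1] <- p[, 2]; p[, n + 2] <- p[, n + 1]
  acc <- matrix(0, n, n)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + p[(1 + di):(n + di), (1 + dj):(n + dj)]
  acc / 9
}
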