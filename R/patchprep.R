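#' CT volume container
#'
#' @param values 3D numeric array of Hounsfield units.
#' @param spacing_mm Positive length-3 voxel spacing (mm).
#' @param origin_mm Length-3 physical coordinate of voxel (1,1,1), mm.
#' @return A `ct_volume` list.
#' @export
ct_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(values)) == 3, all(dim(values) > 0),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            length(origin_mm) == 3)
  structure(list(values = values, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume %s, spacing %s mm>\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x")))
  invisible(x)
}

#' Read a CT volume from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume()] with spacing taken from the header.
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  v <- as.array(img)
  if (length(dim(v)) == 4) v <- v[, , , 1]
  ct_volume(v, RNifti::pixdim(img)[1:3])
}

#' Read nodule centre marks from CSV
#'
#' Expected columns: `subject_id`, `x_mm`, `y_mm`, `z_mm` and optionally
#' `slice` (axial slice index after resampling).
#'
#' @param path CSV file path.
#' @return A data frame of marks.
#' @export
read_marks_csv <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(m)))
    stop("marks CSV must contain columns: ", paste(need, collapse = ", "))
  m
}

#' Resample a CT volume to an isotropic grid with cubic splines
#'
#' Separable natural cubic spline interpolation along each axis in turn,
#' preserving the physical extent of the volume; spline overshoot is clamped
#' to the input intensity range.
#'
#' @param volume A [ct_volume()].
#' @param target_spacing_mm Isotropic target spacing (default 0.5 mm).
#' @return A [ct_volume()] with spacing `(t, t, t)`.
#' @export
resample_isotropic <- function(volume, target_spacing_mm = 0.5) {
  stopifnot(inherits(volume, "ct_volume"))
  if (target_spacing_mm <= 0)
    stop("resample_isotropic: target spacing must be positive")
  v <- volume$values
  rng <- range(v)
  for (axis in 1:3) {
    sp <- volume$spacing_mm[axis]
    n <- dim(v)[axis]
    old <- (seq_len(n) - 1) * sp
    n_new <- max(1L, as.integer(round((n - 1) * sp / target_spacing_mm)) + 1L)
    new <- (seq_len(n_new) - 1) * target_spacing_mm
    new <- pmin(new, old[n])   # stay within the physical extent
    if (n == 1L) {
      v <- rep_axis(v, axis, n_new)
    } else {
      v <- apply_axis_interp(v, axis, old, new)
    }
  }
  v[v < rng[1]] <- rng[1]
  v[v > rng[2]] <- rng[2]
  ct_volume(v, rep(target_spacing_mm, 3), volume$origin_mm)
}

# interpolate along one axis of a 3D array with natural cubic splines
apply_axis_interp <- function(v, axis, old, new) {
  d <- dim(v)
  perm <- c(axis, setdiff(1:3, axis))
  vp <- aperm(v, perm)
  m <- matrix(vp, d[axis], prod(d[-axis]))
  out <- matrix(0, length(new), ncol(m))
  for (j in seq_len(ncol(m))) {
    f <- stats::splinefun(old, m[, j], method = "natural")
    out[, j] <- f(new)
  }
  newdim <- d; newdim[axis] <- length(new)
  res <- array(out, newdim[perm])
  aperm(res, order(perm))
}

rep_axis <- function(v, axis, n_new) {
  d <- dim(v)
  perm <- c(axis, setdiff(1:3, axis))
  vp <- aperm(v, perm)
  m <- matrix(vp, d[axis], prod(d[-axis]))
  out <- m[rep(1L, n_new), , drop = FALSE]
  newdim <- d; newdim[axis] <- n_new
  aperm(array(out, newdim[perm]), order(perm))
}

#' Extract a square nodule ROI from a resampled volume
#'
#' The marked physical centre is converted to 0-based voxel indices by
#' nearest rounding; the ROI spans the half-open index range
#' `[c - side/2, c + side/2)` on each in-plane axis, placing the centre voxel
#' at position `side/2` (index 32 of 64 for the default geometry). An ROI
#' that would leave the volume raises an error rather than being padded.
#'
#' @param volume A [ct_volume()], typically 0.5 mm isotropic.
#' @param mark One row of a marks data frame (`x_mm`, `y_mm`, `z_mm`,
#'   optional `slice`), or a list with those fields.
#' @param side_mm ROI side length in mm (default 32).
#' @return The raw-HU patch as a matrix with a `center_index` attribute; pass
#'   through [normalize_intensity()] to obtain an [image_patch()].
#' @export
extract_roi <- function(volume, mark, side_mm = 32) {
  stopifnot(inherits(volume, "ct_volume"))
  sp <- volume$spacing_mm
  half <- as.integer(round(side_mm / sp[1] / 2))
  n_px <- 2L * half
  ctr <- c(mark$x_mm, mark$y_mm, mark$z_mm)
  idx0 <- round((ctr - volume$origin_mm) / sp)   # 0-based
  k <- if (!is.null(mark$slice) && !is.na(mark$slice)) as.integer(mark$slice)
       else as.integer(idx0[3])
  d <- dim(volume$values)
  if (k < 0 || k >= d[3]) stop("extract_roi: slice index outside volume")
  i0 <- idx0[1] - half; i1 <- idx0[1] + half - 1
  j0 <- idx0[2] - half; j1 <- idx0[2] + half - 1
  if (i0 < 0 || j0 < 0 || i1 >= d[1] || j1 >= d[2])
    stop("extract_roi: ROI exceeds volume bounds (no padding is applied)")
  patch <- volume$values[(i0:i1) + 1L, (j0:j1) + 1L, k + 1L]
  structure(patch, center_index = c(half, half),
            pixel_spacing_mm = sp[1], dim = c(n_px, n_px))
}

#' Window and normalize a HU patch to `[0, 1]`
#'
#' Affine map of `[window[1], window[2]]` onto `[0, 1]`, clipping outside the
#' window. The default (-1000, 400) is a standard lung display window.
#'
#' @param patch Numeric matrix of Hounsfield units.
#' @param window Length-2 increasing numeric window.
#' @param pixel_spacing_mm Spacing of the returned patch (default taken from
#'   the input attribute or 0.5).
#' @return An [image_patch()].
#' @export
normalize_intensity <- function(patch, window = c(-1000, 400),
                                pixel_spacing_mm = NULL) {
  if (length(window) != 2 || !(window[1] < window[2]))
    stop("normalize_intensity: window must satisfy lower < upper")
  sp <- pixel_spacing_mm %||% attr(patch, "pixel_spacing_mm") %||% 0.5
  v <- (as.matrix(patch) - window[1]) / (window[2] - window[1])
  image_patch(pmin(pmax(v, 0), 1), sp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
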