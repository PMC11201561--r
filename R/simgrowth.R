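#' Simulator settings for synthetic nodule growth
#'
#' Defaults emulate the composition of a screening cohort: baseline
#' equivalent diameters 4-30 mm (log-uniform; screening nodules are mostly
#' small), malignant volume doubling times 180-1460 days (log-uniform over
#' the six-months-to-four-years range typical of screen-detected cancers),
#' margin and attenuation class frequencies taken from published
#' screening-cohort tables (spiculation far more common in cancers), and
#' benign nodules exactly stable unless `benign_jitter` is enabled.
#'
#' @param diameter_range_mm Baseline diameter bounds, mm.
#' @param vdt_range_days Malignant volume doubling time bounds, days.
#' @param p_spiculated Probability of a spiculated margin, named for the two
#'   labels.
#' @param p_attenuation 3-vector of class probabilities (solid, ground_glass,
#'   mixed) per label, as a 2-row matrix.
#' @param noise_sd Additive per-scan noise standard deviation (intensity
#'   units on the `[0, 1]` display scale).
#' @param background_level,background_sd,background_smooth_px Correlated
#'   parenchyma-like background field: mean level, amplitude, Gaussian
#'   smoothing radius in pixels.
#' @param edge_softness_mm Sigmoid edge scale of the nodule profile, mm.
#' @param max_offset_mm Maximum |center offset| per axis, mm.
#' @param benign_jitter If `TRUE`, benign follow-up diameters get a +-10%
#'   uniform jitter instead of exact stability.
#' @return A list of settings consumed by [sample_nodule_params()].
#' @export
simulator_config <- function(diameter_range_mm = c(4, 30),
                             vdt_range_days = c(180, 1460),
                             p_spiculated = c(malignant = 0.42, benign = 0.09),
                             p_attenuation = rbind(
                               malignant = c(solid = 0.70, ground_glass = 0.21, mixed = 0.09),
                               benign    = c(solid = 0.83, ground_glass = 0.13, mixed = 0.04)),
                             noise_sd = 0.02,
                             background_level = 0.15,
                             background_sd = 0.03,
                             background_smooth_px = 2,
                             edge_softness_mm = 0.35,
                             max_offset_mm = 2,
                             benign_jitter = FALSE) {
  if (diameter_range_mm[1] > diameter_range_mm[2] ||
      diameter_range_mm[1] < 4 || diameter_range_mm[2] > 30)
    stop("simulator_config: diameter_range_mm must be increasing within [4, 30]")
  if (vdt_range_days[1] > vdt_range_days[2] ||
      vdt_range_days[1] < 180 || vdt_range_days[2] > 1460)
    stop("simulator_config: vdt_range_days must be increasing within [180, 1460]")
  as.list(environment())
}

#' Draw the parameters of one synthetic nodule
#'
#' Deterministic function of `(seed, label, config)`: all draws come from a
#' local RNG stream seeded with `seed`; the global RNG state is untouched.
#'
#' @param seed Non-negative integer seed for this nodule.
#' @param label `"benign"` or `"malignant"`.
#' @param config A [simulator_config()].
#' @return A `nodule_params` list: `diameter_mm`, `malignant`, `vdt_days`
#'   (`NA` for benign), `margin`, `spicule_count`, `attenuation`,
#'   `peak_intensity`, `center_offset_mm`, `noise_sd`, `seed`, plus rendering
#'   settings copied from the config.
#' @export
sample_nodule_params <- function(seed, label = c("benign", "malignant"),
                                 config = simulator_config()) {
  label <- match.arg(label)
  stopifnot(length(seed) == 1L, seed >= 0)
  malignant <- label == "malignant"
  p <- with_local_seed(derive_seed(seed, 0L), {
    dr <- log(config$diameter_range_mm)
    diameter <- exp(runif(1, dr[1], dr[2]))
    vdt <- if (malignant) {
      vr <- log(config$vdt_range_days)
      exp(runif(1, vr[1], vr[2]))
    } else NA_real_
    spiculated <- runif(1) < config$p_spiculated[[label]]
    att_p <- config$p_attenuation[label, ]
    attenuation <- sample(colnames(config$p_attenuation), 1, prob = att_p)
    peak <- switch(attenuation,
                   solid = runif(1, 0.70, 0.95),
                   ground_glass = runif(1, 0.30, 0.45),
                   mixed = runif(1, 0.75, 0.90))
    list(diameter_mm = diameter,
         malignant = malignant,
         vdt_days = vdt,
         margin = if (spiculated) "spiculated" else "smooth",
         spicule_count = if (spiculated) sample(5:9, 1) else 0L,
         attenuation = attenuation,
         peak_intensity = peak,
         center_offset_mm = runif(2, -config$max_offset_mm, config$max_offset_mm),
         benign_growth_factor = if (!malignant && isTRUE(config$benign_jitter))
           runif(1, 0.9, 1.1) else 1,
         noise_sd = config$noise_sd,
         seed = as.integer(seed))
  })
  p <- c(p, config[c("background_level", "background_sd",
                     "background_smooth_px", "edge_softness_mm")])
  class(p) <- "nodule_params"
  validate_nodule_params(p)
  p
}

validate_nodule_params <- function(p) {
  stopifnot(p$diameter_mm >= 4, p$diameter_mm <= 30,
            p$spicule_count >= 0, p$noise_sd >= 0,
            p$peak_intensity > 0, p$peak_intensity <= 1)
  if (p$malignant) {
    if (!is.finite(p$vdt_days) || p$vdt_days < 180 || p$vdt_days > 1460)
      stop("malignant nodule requires vdt_days in [180, 1460]")
  } else if (!is.na(p$vdt_days)) {
    stop("benign nodule must have vdt_days = NA")
  }
  if (p$margin == "smooth" && p$spicule_count != 0)
    stop("smooth margin requires spicule_count = 0")
  invisible(p)
}

#' Current diameter of a nodule under the doubling-time growth law
#'
#' Malignant diameters grow as `d0 * 2^(days / (3 * vdt))` (volume doubles
#' every `vdt` days, so diameter doubles every `3 * vdt`); benign diameters
#' stay at `d0` (or drift by the sampled jitter factor when enabled).
#'
#' @param params A `nodule_params`.
#' @param elapsed_months Months since baseline.
#' @return Diameter in mm; attribute `clipped` is `TRUE` if the 30 mm ceiling
#'   was applied.
#' @export
diameter_at <- function(params, elapsed_months) {
  stopifnot(elapsed_months >= 0)
  days <- elapsed_months * 365.25 / 12
  d <- if (params$malignant) {
    params$diameter_mm * 2^(days / (3 * params$vdt_days))
  } else {
    f <- params$benign_growth_factor
    params$diameter_mm * (1 + (f - 1) * elapsed_months / 12)
  }
  clipped <- d > 30
  structure(min(d, 30), clipped = clipped)
}

#' Render a synthetic nodule patch
#'
#' Paints a radially smooth nodule (sigmoid-edged disk; spiculated margins
#' add narrow radial spikes that scale with the nodule) on a correlated
#' parenchyma-like background, then adds per-scan noise. The background field
#' and spicule geometry are seeded per nodule and persist across time points
#' (same anatomy at follow-up); the additive noise is re-drawn per time point
#' (a new scan).
#'
#' @param params A `nodule_params` from [sample_nodule_params()].
#' @param elapsed_months Months since baseline (`>= 0`).
#' @param add_noise Set `FALSE` for a noise-free render.
#' @return An [image_patch()]; attribute `clipped` flags diameter clipping.
#' @export
render_patch <- function(params, elapsed_months = 0, add_noise = TRUE) {
  stopifnot(inherits(params, "nodule_params"), elapsed_months >= 0)
  n <- 64L; sp <- 0.5
  d <- diameter_at(params, elapsed_months)
  scale_fac <- d / params$diameter_mm
  # pixel-centre coordinates in mm relative to the patch centre
  coord <- (seq_len(n) - (n + 1) / 2) * sp
  cx <- params$center_offset_mm[1]; cy <- params$center_offset_mm[2]
  X <- matrix(coord, n, n) - cx
  Y <- matrix(coord, n, n, byrow = TRUE) - cy
  r <- sqrt(X^2 + Y^2)
  theta <- atan2(Y, X)

  R0 <- params$diameter_mm / 2
  Rtheta <- matrix(R0, n, n)
  if (params$spicule_count > 0) {
    geo <- with_local_seed(derive_seed(params$seed, 1L), list(
      ang = runif(params$spicule_count, 0, 2 * pi),
      len = runif(params$spicule_count, 0.25, 0.45),
      wid = runif(params$spicule_count, 0.06, 0.12)))
    for (s in seq_len(params$spicule_count)) {
      dth <- atan2(sin(theta - geo$ang[s]), cos(theta - geo$ang[s]))
      Rtheta <- Rtheta + R0 * geo$len[s] * exp(-0.5 * (dth / geo$wid[s])^2)
    }
  }
  Rtheta <- Rtheta * scale_fac   # shape fixed, scale follows the growth law

  soft <- params$edge_softness_mm
  fg <- params$peak_intensity * stats::plogis((Rtheta - r) / soft)
  if (params$attenuation == "mixed") {
    outer_peak <- 0.35
    core <- stats::plogis((0.55 * Rtheta - r) / soft)
    fg <- outer_peak * stats::plogis((Rtheta - r) / soft) +
      (params$peak_intensity - outer_peak) * core
  }

  bg <- with_local_seed(derive_seed(params$seed, 2L), {
    field <- matrix(rnorm(n * n), n, n)
    field <- gaussian_blur(field, params$background_smooth_px)
    s <- sd(field)
    if (s > 0) field <- field / s
    params$background_level + params$background_sd * field
  })

  img <- bg + fg
  if (add_noise && params$noise_sd > 0) {
    tp <- as.integer(round(elapsed_months * 100))
    img <- img + with_local_seed(derive_seed(params$seed, 3L + tp),
                                 matrix(rnorm(n * n, 0, params$noise_sd), n, n))
  }
  out <- image_patch(pmin(pmax(img, 0), 1), sp)
  attr(out, "clipped") <- isTRUE(attr(d, "clipped"))
  out
}

#' Generate a baseline/follow-up pair for one nodule
#'
#' @param params A `nodule_params`.
#' @param interval_months Scan interval (default 12, the annual screening
#'   round).
#' @param subject_id Optional subject identifier string.
#' @return A `nodule_pair` list: `baseline`, `followup` ([image_patch()]s),
#'   `interval_months`, `label`, `subject_id`, `params`.
#' @export
generate_pair <- function(params, interval_months = 12, subject_id = NA_character_) {
  stopifnot(interval_months > 0)
  pair <- list(baseline = render_patch(params, 0),
               followup = render_patch(params, interval_months),
               interval_months = interval_months,
               label = if (params$malignant) "malignant" else "benign",
               subject_id = subject_id,
               params = params)
  class(pair) <- "nodule_pair"
  pair
}

#' Generate a synthetic paired-patch dataset
#'
#' Per-nodule seeds are derived from the master seed with an integer hash, so
#' the dataset is reproducible and individual nodules are independent.
#'
#' @param n_malignant,n_benign Pair counts (`>= 0`).
#' @param seed Master seed.
#' @param config A [simulator_config()].
#' @param interval_months Scan interval for every pair.
#' @return A `nodule_dataset`: list of `nodule_pair`s with a `labels`
#'   attribute (character vector).
#' @export
generate_dataset <- function(n_malignant, n_benign, seed,
                             config = simulator_config(),
                             interval_months = 12) {
  if (n_malignant < 0 || n_benign < 0)
    stop("generate_dataset: counts must be non-negative")
  labels <- c(rep("malignant", n_malignant), rep("benign", n_benign))
  pairs <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    p <- sample_nodule_params(derive_seed(seed, i), labels[i], config)
    id <- sprintf("%s%04d", if (labels[i] == "malignant") "M" else "B", i)
    pairs[[i]] <- generate_pair(p, interval_months, id)
  }
  structure(pairs, labels = labels, class = "nodule_dataset")
}

#' @export
print.nodule_dataset <- function(x, ...) {
  lab <- attr(x, "labels")
  cat(sprintf("<nodule_dataset: %d pairs (%d malignant, %d benign)>\n",
              length(x), sum(lab == "malignant"), sum(lab == "benign")))
  invisible(x)
}

#' Write a nodule dataset to disk
#'
#' One file per patch (`png`: 8-bit grayscale PNG; `csv`: plain-text matrix)
#' plus a `manifest.csv` with subject id, label, interval and file paths.
#'
#' @param dataset A `nodule_dataset`.
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"csv"`.
#' @return The manifest data frame, invisibly.
#' @export
write_nodule_dataset <- function(dataset, dir, format = c("png", "csv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset, function(pair) {
    files <- vapply(c("baseline", "followup"), function(which) {
      fn <- sprintf("%s_%s.%s", pair$subject_id, which, format)
      path <- file.path(dir, fn)
      if (format == "png") {
        png::writePNG(patch_values(pair[[which]]), path)
      } else {
        write.table(patch_values(pair[[which]]), path, sep = ",",
                    row.names = FALSE, col.names = FALSE)
      }
      fn
    }, character(1))
    data.frame(subject_id = pair$subject_id, label = pair$label,
               interval_months = pair$interval_months,
               baseline_file = files[1], followup_file = files[2],
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a nodule dataset written by [write_nodule_dataset()]
#' @param dir Dataset directory containing `manifest.csv`.
#' @return A `nodule_dataset` (without simulator params).
#' @export
read_nodule_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  pairs <- lapply(seq_len(nrow(manifest)), function(i) {
    read_one <- function(fn) {
      path <- file.path(dir, fn)
      v <- if (grepl("\\.png$", fn)) {
        img <- png::readPNG(path)
        if (length(dim(img)) == 3) img[, , 1] else img
      } else {
        as.matrix(read.csv(path, header = FALSE))
      }
      image_patch(matrix(as.numeric(v), nrow(v), ncol(v)))
    }
    pair <- list(baseline = read_one(manifest$baseline_file[i]),
                 followup = read_one(manifest$followup_file[i]),
                 interval_months = manifest$interval_months[i],
                 label = manifest$label[i],
                 subject_id = manifest$subject_id[i],
                 params = NULL)
    class(pair) <- "nodule_pair"
    pair
  })
  structure(pairs, labels = manifest$label, class = "nodule_dataset")
}

# run expr with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  n <- nrow(m)
  # separable filtering with replicated edges via a banded matrix
  idx <- outer(seq_len(n), -half:half, `+`)
  idx[idx < 1] <- 1; idx[idx > n] <- n
  K <- matrix(0, n, n)
  for (j in seq_along(k)) K[cbind(seq_len(n), idx[, j])] <- K[cbind(seq_len(n), idx[, j])] + k[j]
  K %*% m %*% t(K)
}
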