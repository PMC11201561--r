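#' Risk score set
#'
#' Per-subject continuous malignancy scores with binary outcome labels
#' (1 = cancer event).
#'
#' @param subject_ids Character vector.
#' @param scores Numeric vector.
#' @param labels 0/1 vector (or logical).
#' @return A `risk_score_set` data frame.
#' @export
risk_score_set <- function(subject_ids, scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(subject_ids) == length(scores),
            length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  structure(data.frame(subject_id = as.character(subject_ids),
                       score = as.numeric(scores), label = labels,
                       stringsAsFactors = FALSE),
            class = c("risk_score_set", "data.frame"))
}

#' Read a risk score set from CSV (columns subject_id, score, label)
#' @param path CSV path.
#' @return A [risk_score_set()].
#' @export
read_scores_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  risk_score_set(d$subject_id, d$score, d$label)
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2)
    stop("both outcome classes must be present")
}

roc_of <- function(scores) {
  check_two_classes(scores$label)
  pROC::roc(response = scores$label, predictor = scores$score,
            levels = c(0, 1), direction = "<", quiet = TRUE)
}

#' Area under the ROC curve with DeLong standard error
#'
#' AUC is the Mann-Whitney concordance probability (ties counted 1/2); the
#' standard error comes from the DeLong structural-components variance.
#'
#' @param scores A [risk_score_set()] containing both classes.
#' @return List with `auc` and `se`.
#' @export
roc_auc <- function(scores) {
  r <- roc_of(scores)
  list(auc = as.numeric(pROC::auc(r)),
       se = sqrt(as.numeric(pROC::var(r, method = "delong"))))
}

#' DeLong test comparing two correlated ROC curves
#'
#' Paired design: both score sets must cover the same subjects with the same
#' labels. Two-sided p-value from the standard normal.
#'
#' @param scores_a,scores_b [risk_score_set()]s over the same subjects.
#' @return List with `auc_a`, `auc_b`, `delta`, `z`, `p`, and `se_delta`.
#' @export
delong_test <- function(scores_a, scores_b) {
  if (!identical(scores_a$subject_id, scores_b$subject_id) ||
      !identical(scores_a$label, scores_b$label))
    stop("delong_test: inputs must be paired (same subjects and labels)")
  ra <- roc_of(scores_a); rb <- roc_of(scores_b)
  tt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  delta <- as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb))
  z <- as.numeric(tt$statistic)
  list(auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
       delta = delta, z = z, p = as.numeric(tt$p.value),
       se_delta = if (z != 0) abs(delta / z) else NA_real_)
}

#' Hochberg step-up adjustment of p-values
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p-values (same order), each `>=` its raw value, capped
#'   at 1, order-preserving.
#' @export
hochberg_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("hochberg_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "hochberg")
}

#' Stratify continuous risk scores into low / medium / high
#'
#' Closed middle interval, as in published threshold rules:
#' `score < t_low` is low, `t_low <= score <= t_high` is medium,
#' `score > t_high` is high. Published rules: Brock
#' (<0.0117, \[0.0117, 0.10\], >0.10); risk-scorer alignment thresholds
#' (<0.45, \[0.45, 0.81\], >0.81).
#'
#' @param scores Numeric vector.
#' @param thresholds Length-2 numeric `c(t_low, t_high)`, `t_low <= t_high`.
#' @return Ordered factor with levels `low < medium < high`.
#' @export
stratify_risk <- function(scores, thresholds) {
  stopifnot(length(thresholds) == 2, thresholds[1] <= thresholds[2])
  g <- ifelse(scores < thresholds[1], "low",
              ifelse(scores <= thresholds[2], "medium", "high"))
  factor(g, levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Stratify Lung-RADS categories into risk groups
#'
#' Categories below 3 are low risk, exactly 3 medium, above 3 high.
#'
#' @param categories Numeric Lung-RADS categories.
#' @return Ordered factor `low < medium < high`.
#' @export
stratify_lungrads <- function(categories) {
  g <- ifelse(categories < 3, "low", ifelse(categories == 3, "medium", "high"))
  factor(g, levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Thresholds matching target subgroup sizes
#'
#' Places `(t_low, t_high)` at order statistics so that stratification by
#' [stratify_risk()] reproduces the requested `(n_low, n_medium, n_high)`
#' exactly when no ties straddle a boundary. When a tied block straddles a
#' boundary, the whole block is absorbed into the lower-side group and the
#' resulting size deviation is reported in the `deviation` attribute.
#'
#' @param scores Numeric vector.
#' @param target_sizes Integer triple summing to `length(scores)`.
#' @return `c(t_low, t_high)` with attributes `sizes` (achieved) and
#'   `deviation` (achieved - target).
#' @export
match_subgroup_thresholds <- function(scores, target_sizes) {
  n <- length(scores)
  if (length(target_sizes) != 3 || any(target_sizes < 0) ||
      sum(target_sizes) != n)
    stop("match_subgroup_thresholds: target sizes must be >= 0 and sum to n")
  s <- sort(scores)
  cut_at <- function(k) {
    # smallest threshold t with #(score < t) >= k, placed between order stats
    if (k <= 0) return(-Inf)
    if (k >= n) return(Inf)
    if (s[k] < s[k + 1]) (s[k] + s[k + 1]) / 2
    else {
      # tied block straddles the boundary: absorb it into the lower group
      above <- s[s > s[k]]
      if (length(above) == 0) Inf else (s[k] + min(above)) / 2
    }
  }
  t_low <- cut_at(target_sizes[1])
  t_high_cut <- cut_at(target_sizes[1] + target_sizes[2])
  # stratify_risk uses a closed middle interval: medium is <= t_high
  t_high <- if (is.infinite(t_high_cut)) Inf else t_high_cut
  thr <- c(t_low = max(t_low, min(s) - 1), t_high = t_high)
  if (thr[1] > thr[2]) thr[1] <- thr[2]
  g <- stratify_risk(scores, thr)
  sizes <- as.integer(table(g))
  structure(thr, sizes = sizes, deviation = sizes - as.integer(target_sizes))
}

#' Reclassification table between two stratifications
#'
#' 3 x 3 migration counts (rows = initial group, columns = new group), kept
#' separately for event (cancer) and nonevent subjects.
#'
#' @param initial,new Ordered factors from [stratify_risk()] (or any factor
#'   with levels low/medium/high), equal length.
#' @param labels 0/1 outcome labels (1 = cancer event).
#' @return A `reclass_table`: `event_counts`, `nonevent_counts`, `n_event`,
#'   `n_nonevent`.
#' @export
reclassification_table <- function(initial, new, labels) {
  if (length(initial) != length(new) || length(new) != length(labels))
    stop("reclassification_table: length mismatch")
  lv <- c("low", "medium", "high")
  initial <- factor(as.character(initial), levels = lv)
  new <- factor(as.character(new), levels = lv)
  labels <- as.integer(labels)
  ev <- table(initial[labels == 1], new[labels == 1])
  ne <- table(initial[labels == 0], new[labels == 0])
  reclass_table(unclass(as.matrix(ev)), unclass(as.matrix(ne)))
}

#' Construct a reclassification table from count matrices
#'
#' @param event_counts,nonevent_counts 3 x 3 non-negative integer matrices,
#'   rows = initial group (low, medium, high), columns = new group.
#' @return A `reclass_table`.
#' @export
reclass_table <- function(event_counts, nonevent_counts) {
  event_counts <- as.matrix(event_counts)
  nonevent_counts <- as.matrix(nonevent_counts)
  stopifnot(all(dim(event_counts) == c(3, 3)),
            all(dim(nonevent_counts) == c(3, 3)),
            all(event_counts >= 0), all(nonevent_counts >= 0))
  dimnames(event_counts) <- dimnames(nonevent_counts) <-
    list(initial = c("low", "medium", "high"),
         new = c("low", "medium", "high"))
  structure(list(event_counts = event_counts,
                 nonevent_counts = nonevent_counts,
                 n_event = sum(event_counts),
                 n_nonevent = sum(nonevent_counts)),
            class = "reclass_table")
}

#' @export
print.reclass_table <- function(x, ...) {
  cat(sprintf("<reclass_table: %d events, %d nonevents>\n",
              x$n_event, x$n_nonevent))
  cat("events:\n"); print(x$event_counts)
  cat("nonevents:\n"); print(x$nonevent_counts)
  invisible(x)
}

up_down <- function(m) {
  # escalations: strictly above the diagonal; de-escalations: strictly below
  list(up = m[1, 2] + m[1, 3] + m[2, 3],
       down = m[2, 1] + m[3, 1] + m[3, 2])
}

#' Net reclassification index
#'
#' `event NRI = (events escalated - events de-escalated) / n_event`;
#' `nonevent NRI = (nonevents de-escalated - nonevents escalated) /
#' n_nonevent`; overall NRI is their exact sum. Escalation is any move to a
#' strictly higher of the three ordered groups (low to high counts once).
#'
#' @param table A `reclass_table`.
#' @return An `nri_result` list: `event_nri`, `nonevent_nri`, `overall_nri`,
#'   movement counts, and ns.
#' @export
nri <- function(table) {
  stopifnot(inherits(table, "reclass_table"))
  if (table$n_event == 0 || table$n_nonevent == 0)
    stop("nri: undefined component (no events or no nonevents)")
  e <- up_down(table$event_counts)
  ne <- up_down(table$nonevent_counts)
  event_nri <- (e$up - e$down) / table$n_event
  nonevent_nri <- (ne$down - ne$up) / table$n_nonevent
  structure(list(event_nri = event_nri, nonevent_nri = nonevent_nri,
                 overall_nri = event_nri + nonevent_nri,
                 event_up = e$up, event_down = e$down,
                 nonevent_up = ne$up, nonevent_down = ne$down,
                 n_event = table$n_event, n_nonevent = table$n_nonevent),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("event NRI %.4f (%d up, %d down of %d); nonevent NRI %.4f (%d down, %d up of %d); overall %.4f\n",
              x$event_nri, x$event_up, x$event_down, x$n_event,
              x$nonevent_nri, x$nonevent_down, x$nonevent_up, x$n_nonevent,
              x$overall_nri))
  invisible(x)
}

#' Z-test for the net reclassification index
#'
#' Component standard errors use the movement-proportion variance
#' `SE = sqrt((p_up + p_down - (p_up - p_down)^2) / n)` per component; the
#' overall statistic combines the two independent component variances.
#' Components with zero movement have an undefined Z, reported as `NA` with
#' p `NA`.
#'
#' @param table A `reclass_table`.
#' @return List of `z` and two-sided `p` for event, nonevent and overall
#'   components, plus the component SEs.
#' @export
nri_z_test <- function(table) {
  r <- nri(table)
  comp <- function(up, down, n) {
    pu <- up / n; pd <- down / n
    v <- (pu + pd - (pu - pd)^2) / n
    if (up + down == 0 || v <= 0) return(c(se = 0, z = NA_real_, p = NA_real_))
    se <- sqrt(v)
    z <- (pu - pd) / se
    c(se = se, z = z, p = 2 * pnorm(-abs(z)))
  }
  ev <- comp(r$event_up, r$event_down, r$n_event)
  # nonevent NRI is (down - up)/n: swap roles so sign(z) = sign(NRI)
  ne <- comp(r$nonevent_down, r$nonevent_up, r$n_nonevent)
  v_all <- ev[["se"]]^2 + ne[["se"]]^2
  if (v_all > 0) {
    z_all <- r$overall_nri / sqrt(v_all)
    p_all <- 2 * pnorm(-abs(z_all))
  } else {
    z_all <- NA_real_; p_all <- NA_real_
  }
  list(z_event = ev[["z"]], p_event = ev[["p"]], se_event = ev[["se"]],
       z_nonevent = ne[["z"]], p_nonevent = ne[["p"]], se_nonevent = ne[["se"]],
       z_overall = z_all, p_overall = p_all, nri = r)
}

# ---- toy downstream risk scorer --------------------------------------------

patch_features <- function(patch) {
  v <- patch_values(patch)
  d <- measure_diameter(patch)
  sm <- smooth_3x3(v)
  n <- nrow(v)
  border <- median(c(v[1, ], v[n, ], v[, 1], v[, n]))
  # edge spikiness: dispersion of the half-max radius across rays
  rads <- ray_radii(sm, border)
  spik <- if (length(rads) > 2 && median(rads) > 0) {
    stats::mad(rads) / median(rads)
  } else 0
  c(diameter = d, mean_int = mean(v), max_int = max(sm), spikiness = spik)
}

ray_radii <- function(v, bg, n_angles = 24) {
  n <- nrow(v)
  half <- bg + 0.5 * (max(v) - bg)
  msk <- v > half
  pk <- if (any(msk)) {
    w <- which(msk, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  } else as.numeric(which(v == max(v), arr.ind = TRUE)[1, ])
  rs <- seq(0, n / 2 - 1, by = 0.5)
  angles <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  out <- vapply(angles, function(a) {
    xi <- pk[1] + rs * cos(a); yi <- pk[2] + rs * sin(a)
    ok <- xi >= 1 & xi <= n & yi >= 1 & yi <= n
    prof <- bilinear_at(v, xi[ok], yi[ok])
    b <- which(prof < half)[1]
    if (is.na(b) || b == 1) NA_real_ else rs[ok][b]
  }, numeric(1))
  out[is.finite(out)]
}

#' Train a toy malignancy risk scorer on patch features
#'
#' A deliberately simple logistic model over four interpretable patch
#' features (apparent diameter, mean and peak intensity, margin spikiness).
#' It stands in for a full risk-prediction model as the downstream task that
#' consumes predicted follow-up patches.
#'
#' @param patches List of [image_patch()]s.
#' @param labels 0/1 outcomes (1 = malignant), both classes present.
#' @param seed Kept for interface stability; the fit itself is deterministic.
#' @return A `toy_scorer` (glm fit + feature scaling).
#' @export
train_toy_scorer <- function(patches, labels, seed = 1) {
  labels <- as.integer(labels)
  check_two_classes(labels)
  feats <- t(vapply(patches, patch_features, numeric(4)))
  mu <- colMeans(feats); sdv <- apply(feats, 2, sd)
  sdv[sdv == 0] <- 1
  z <- scale(feats, mu, sdv)
  df <- data.frame(z, y = labels)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  structure(list(fit = fit, mu = mu, sd = sdv, seed = seed),
            class = "toy_scorer")
}

#' Score patches with a toy scorer
#'
#' @param scorer A [train_toy_scorer()] result.
#' @param patches List of patches.
#' @param subject_ids Optional ids (default `S1..Sn`).
#' @param labels Optional 0/1 outcomes to attach (defaults to all 0).
#' @return A [risk_score_set()] with scores in `[0, 1]`.
#' @export
score_patches <- function(scorer, patches, subject_ids = NULL, labels = NULL) {
  feats <- t(vapply(patches, patch_features, numeric(4)))
  z <- scale(feats, scorer$mu, scorer$sd)
  p <- as.numeric(predict(scorer$fit, newdata = data.frame(z),
                          type = "response"))
  ids <- subject_ids %||% paste0("S", seq_along(patches))
  risk_score_set(ids, p, labels %||% rep(0L, length(patches)))
}
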