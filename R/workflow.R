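#' Experiment configuration for the end-to-end synthetic study
#'
#' Bundles simulator, training and evaluation settings with explicit seeds.
#' The default is the smoke-scale profile (64 training pairs, 200 generator
#' steps, 32 test pairs, compact networks) that the package's own end-to-end
#' checks run; `full_scale = TRUE` switches to a synthetic cohort mirroring
#' the published screening split (776 training / 450 test subjects) with the
#' default full-size networks -- substantially slower.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param full_scale Use the full synthetic cohort profile.
#' @param iterations Generator steps.
#' @param n_critic Critic steps per generator step.
#' @param batch_size Minibatch size.
#' @param lr,betas Adam settings for the smoke profile (the full profile uses
#'   the conventional 1e-4).
#' @param weights A [loss_weights()].
#' @param predictor_depth,predictor_base,critic_base,extractor_base
#'   Architecture sizes.
#' @param n_train_malignant,n_train_benign,n_test_malignant,n_test_benign
#'   Cohort composition.
#' @param interval_months Scan interval.
#' @param sim Simulator settings ([simulator_config()]).
#' @param strata_fractions Target fractions of the low/medium/high groups
#'   used for score stratification (sizes are matched between the initial and
#'   new stratification, as in threshold-alignment evaluation designs).
#' @param scorer_seed Toy-scorer seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(seed = 1, full_scale = FALSE,
                              iterations = if (full_scale) 2000 else 200,
                              n_critic = 5,
                              batch_size = 8,
                              lr = if (full_scale) 1e-4 else 1e-3,
                              betas = c(0.5, 0.9),
                              weights = loss_weights(),
                              predictor_depth = if (full_scale) 4 else 3,
                              predictor_base = if (full_scale) 32 else 8,
                              critic_base = if (full_scale) 32 else 8,
                              extractor_base = if (full_scale) 16 else 8,
                              n_train_malignant = if (full_scale) 165 else 14,
                              n_train_benign = if (full_scale) 611 else 50,
                              n_test_malignant = if (full_scale) 53 else 8,
                              n_test_benign = if (full_scale) 397 else 24,
                              interval_months = 12,
                              sim = simulator_config(),
                              strata_fractions = c(0.5, 0.35, 0.15),
                              scorer_seed = 9) {
  cfg <- as.list(environment())
  class(cfg) <- "experiment_config"
  cfg
}

#' Run the full synthetic experiment
#'
#' simulate -> train -> predict -> score -> stratify -> reclassify:
#' generates train/test synthetic cohorts, trains the adversarial growth
#' predictor, predicts follow-up patches ("GP-nodules") for the test
#' baselines, scores baseline / GP-nodule / real follow-up patches with the
#' toy risk scorer (AUC for each condition), stratifies baseline and
#' GP-nodule scores into size-matched risk groups, and reports the
#' reclassification table with NRI and Z-statistics. Rerunning with the same
#' config reproduces every number.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory for the report (JSON), loss history
#'   (CSV) and manifest (JSON).
#' @return An `experiment_report` list.
#' @export
run_synthetic_experiment <- function(config = experiment_config(),
                                     out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  train_ds <- stage("simulate", generate_dataset(
    config$n_train_malignant, config$n_train_benign,
    seed = derive_seed(config$seed, 1L), config = config$sim,
    interval_months = config$interval_months))
  test_ds <- stage("simulate", generate_dataset(
    config$n_test_malignant, config$n_test_benign,
    seed = derive_seed(config$seed, 2L), config = config$sim,
    interval_months = config$interval_months))

  tcfg <- train_config(weights = config$weights,
                       iterations = config$iterations,
                       n_critic = config$n_critic,
                       batch_size = config$batch_size,
                       lr = config$lr, betas = config$betas,
                       seed = derive_seed(config$seed, 3L),
                       predictor_depth = config$predictor_depth,
                       predictor_base = config$predictor_base,
                       critic_base = config$critic_base,
                       extractor_base = config$extractor_base)
  state <- stage("train", train(train_ds, tcfg))
  predictor <- freeze_predictor(state$predictor)

  test_base <- lapply(test_ds, `[[`, "baseline")
  test_fu <- lapply(test_ds, `[[`, "followup")
  gp <- stage("predict", predict_followup(predictor, test_base))

  labels_train <- as.integer(attr(train_ds, "labels") == "malignant")
  labels_test <- as.integer(attr(test_ds, "labels") == "malignant")
  ids <- vapply(test_ds, `[[`, character(1), "subject_id")
  scorer <- stage("score", train_toy_scorer(
    lapply(train_ds, `[[`, "followup"), labels_train,
    seed = derive_seed(config$seed, 4L)))
  sc_base <- score_patches(scorer, test_base, ids, labels_test)
  sc_gp <- score_patches(scorer, gp, ids, labels_test)
  sc_fu <- score_patches(scorer, test_fu, ids, labels_test)
  aucs <- stage("score", list(baseline = roc_auc(sc_base),
                              gp_nodule = roc_auc(sc_gp),
                              followup = roc_auc(sc_fu)))

  n <- length(test_ds)
  sizes <- round(config$strata_fractions / sum(config$strata_fractions) * n)
  sizes[3] <- n - sizes[1] - sizes[2]
  thr0 <- stage("stratify", match_subgroup_thresholds(sc_base$score, sizes))
  initial <- stratify_risk(sc_base$score, thr0)
  thr1 <- stage("stratify", match_subgroup_thresholds(
    sc_gp$score, as.integer(table(initial))))
  new <- stratify_risk(sc_gp$score, thr1)
  tab <- stage("reclassify", reclassification_table(initial, new, labels_test))
  zt <- stage("reclassify", nri_z_test(tab))

  mal <- labels_test == 1
  ssim_gp <- vapply(which(mal), function(i) image_ssim(gp[[i]], test_fu[[i]]),
                    numeric(1))
  ssim_base <- vapply(which(mal), function(i)
    image_ssim(test_base[[i]], test_fu[[i]]), numeric(1))
  mse_gp <- vapply(seq_len(n), function(i) image_mse(gp[[i]], test_fu[[i]]),
                   numeric(1))
  ssim_all <- vapply(seq_len(n), function(i) image_ssim(gp[[i]], test_fu[[i]]),
                     numeric(1))

  h <- state$history
  if (is.null(h)) h <- data.frame(step = integer(0), l1 = numeric(0))
  k <- min(20, nrow(h))
  loss_prog <- if (k > 0) {
    list(l1_first = mean(h$l1[seq_len(k)]),
         l1_last = mean(h$l1[seq(nrow(h) - k + 1, nrow(h))]))
  } else list(l1_first = NA_real_, l1_last = NA_real_)
  report <- structure(list(
    aucs = aucs,
    nri = zt$nri,
    z_test = zt,
    reclass_table = tab,
    image_metrics = list(
      mean_mse_gp = mean(mse_gp),
      mean_ssim_gp = mean(ssim_all),
      mean_ssim_gp_malignant = mean(ssim_gp),
      mean_ssim_baseline_malignant = mean(ssim_base)),
    loss_progress = loss_prog,
    history = h,
    manifest = list(seed = config$seed,
                    config_hash = config_hash(strip_functions(config)),
                    package_version = as.character(utils::packageVersion("nodulegp")),
                    r_version = as.character(getRversion()),
                    n_train = length(train_ds), n_test = n,
                    iterations = config$iterations)),
    class = "experiment_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(h, file.path(out_dir, "history.csv"), row.names = FALSE)
    jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

strip_functions <- function(x) {
  if (is.list(x)) lapply(x[!vapply(x, is.function, logical(1))], strip_functions)
  else x
}

#' Flatten an experiment report to plain numbers
#' @param report An `experiment_report`.
#' @return A named list of scalars suitable for JSON serialization.
#' @export
report_summary <- function(report) {
  list(auc_baseline = report$aucs$baseline$auc,
       auc_gp_nodule = report$aucs$gp_nodule$auc,
       auc_followup = report$aucs$followup$auc,
       event_nri = report$nri$event_nri,
       nonevent_nri = report$nri$nonevent_nri,
       overall_nri = report$nri$overall_nri,
       mean_mse_gp = report$image_metrics$mean_mse_gp,
       mean_ssim_gp = report$image_metrics$mean_ssim_gp,
       mean_ssim_gp_malignant = report$image_metrics$mean_ssim_gp_malignant,
       mean_ssim_baseline_malignant = report$image_metrics$mean_ssim_baseline_malignant,
       l1_first = report$loss_progress$l1_first,
       l1_last = report$loss_progress$l1_last,
       config_hash = report$manifest$config_hash)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Synthetic growth-prediction experiment\n")
  cat(sprintf("  AUC baseline %.3f | GP-nodule %.3f | follow-up %.3f\n",
              x$aucs$baseline$auc, x$aucs$gp_nodule$auc, x$aucs$followup$auc))
  cat(sprintf("  NRI event %.3f, nonevent %.3f, overall %.3f\n",
              x$nri$event_nri, x$nri$nonevent_nri, x$nri$overall_nri))
  cat(sprintf("  SSIM(GP, follow-up) malignant %.3f vs SSIM(baseline, follow-up) %.3f\n",
              x$image_metrics$mean_ssim_gp_malignant,
              x$image_metrics$mean_ssim_baseline_malignant))
  cat(sprintf("  L1 first/last 20 steps: %.4f -> %.4f\n",
              x$loss_progress$l1_first, x$loss_progress$l1_last))
  invisible(x)
}
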