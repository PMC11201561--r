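test_that("AUC equals the all-pairs concordance oracle and handles symmetry", {
  perfect <- risk_score_set(1:4, c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(suppressWarnings(roc_auc(perfect))$auc, 1.0)
  set.seed(201)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 2)   # rounding provokes ties
    rs <- risk_score_set(seq_len(n), scores, labels)
    expect_equal(roc_auc(rs)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
    flipped <- risk_score_set(seq_len(n), scores, 1 - labels)
    expect_equal(roc_auc(flipped)$auc, 1 - roc_auc(rs)$auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(risk_score_set(1:3, 1:3, c(1, 1, 1))), "class")
})

test_that("DeLong comparison is null on identical scores and signs follow the AUC difference", {
  set.seed(202)
  n <- 40
  labels <- c(rep(1, 12), rep(0, 28))
  s <- runif(n)
  a <- risk_score_set(seq_len(n), s, labels)
  same <- delong_test(a, a)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  b <- risk_score_set(seq_len(n), runif(n), labels)
  tt <- delong_test(a, b)
  expect_equal(sign(tt$z), sign(tt$delta))
  expect_error(delong_test(a, risk_score_set(seq_len(n), s, rev(labels))),
               "paired")
})

test_that("DeLong variance of the AUC difference agrees with a bootstrap oracle", {
  set.seed(203)
  n <- 40
  labels <- c(rep(1, 15), rep(0, 25))
  latent <- rnorm(n, labels)
  sa <- latent + rnorm(n, 0, 0.8)
  sb <- latent + rnorm(n, 0, 0.8)
  a <- risk_score_set(seq_len(n), sa, labels)
  b <- risk_score_set(seq_len(n), sb, labels)
  tt <- delong_test(a, b)
  deltas <- replicate(20000, {
    idx <- sample.int(n, n, replace = TRUE)
    while (length(unique(labels[idx])) < 2)
      idx <- sample.int(n, n, replace = TRUE)
    oracle_auc_fast(sa[idx], labels[idx]) - oracle_auc_fast(sb[idx], labels[idx])
  })
  expect_lt(abs(tt$se_delta^2 - var(deltas)) / var(deltas), 0.15)
})

test_that("Hochberg adjustment matches the step-up definition and dominates raw p", {
  expect_equal(hochberg_adjust(0.03), 0.03)
  set.seed(204)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    adj <- hochberg_adjust(p)
    expect_equal(adj, oracle_hochberg(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_identical(order(adj[order(p)]), seq_along(p))  # order preserved
  }
  same <- hochberg_adjust(rep(0.02, 4))
  expect_equal(same, oracle_hochberg(rep(0.02, 4)))
  expect_error(hochberg_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("risk stratification applies the published closed-middle threshold rules", {
  lcrp <- stratify_risk(c(0.44, 0.45, 0.81, 0.811), c(0.45, 0.81))
  expect_identical(as.character(lcrp), c("low", "medium", "medium", "high"))
  brock <- stratify_risk(c(0.0116, 0.0117, 0.10, 0.11), c(0.0117, 0.10))
  expect_identical(as.character(brock), c("low", "medium", "medium", "high"))
  expect_length(stratify_risk(numeric(0), c(0.1, 0.2)), 0)
  lr <- stratify_lungrads(c(1, 2, 3, 4, 4))
  expect_identical(as.character(lr), c("low", "low", "medium", "high", "high"))
  # monotone: a higher score never lands in a lower group
  set.seed(205)
  s <- sort(runif(50))
  g <- stratify_risk(s, c(0.3, 0.7))
  expect_true(all(diff(as.integer(g)) >= 0))
})

test_that("threshold matching reproduces target subgroup sizes and reports tie absorption", {
  set.seed(206)
  s <- runif(100)
  thr <- match_subgroup_thresholds(s, c(30, 50, 20))
  expect_identical(attr(thr, "sizes"), c(30L, 50L, 20L))
  expect_identical(attr(thr, "deviation"), c(0L, 0L, 0L))
  # fixed point: matching an existing stratification's sizes reproduces it
  g0 <- stratify_risk(s, c(0.35, 0.8))
  thr2 <- match_subgroup_thresholds(s, as.integer(table(g0)))
  expect_identical(stratify_risk(s, thr2), g0)
  # degenerate ties: the tied block is absorbed into the low-side group
  tied <- match_subgroup_thresholds(c(1, 1), c(1, 1, 0))
  expect_true(any(attr(tied, "deviation") != 0))
  expect_error(match_subgroup_thresholds(s, c(10, 10, 10)), "sum")
})

test_that("reclassification tables count migrations by outcome and ignore subject order", {
  set.seed(207)
  n <- 60
  labels <- sample(0:1, n, replace = TRUE, prob = c(0.8, 0.2))
  g1 <- factor(sample(c("low", "medium", "high"), n, replace = TRUE),
               levels = c("low", "medium", "high"), ordered = TRUE)
  g2 <- factor(sample(c("low", "medium", "high"), n, replace = TRUE),
               levels = c("low", "medium", "high"), ordered = TRUE)
  tab <- reclassification_table(g1, g2, labels)
  expect_equal(sum(tab$event_counts) + sum(tab$nonevent_counts), n)
  perm <- sample.int(n)
  tab_p <- reclassification_table(g1[perm], g2[perm], labels[perm])
  expect_identical(tab$event_counts, tab_p$event_counts)
  expect_identical(tab$nonevent_counts, tab_p$nonevent_counts)
  # identity reclassification concentrates all mass on the diagonal
  tab_id <- reclassification_table(g1, g1, labels)
  expect_identical(sum(diag(tab_id$event_counts)), tab_id$n_event)
  expect_error(reclassification_table(g1, g2[-1], labels), "length")
})

test_that("NRI components obey their identity, bounds and the permutation null", {
  tabs <- reference_reclass_tables()
  for (tb in tabs) {
    r <- nri(tb)
    expect_equal(r$overall_nri, r$event_nri + r$nonevent_nri)
    expect_true(abs(r$event_nri) <= 1 && abs(r$nonevent_nri) <= 1)
  }
  # identity table: zero everywhere
  idt <- reclass_table(diag(c(5, 5, 5)), diag(c(10, 10, 10)))
  r0 <- nri(idt)
  expect_identical(r0$overall_nri, 0)
  # uniformly random regrouping has mean NRI ~ 0
  set.seed(208)
  lv <- c("low", "medium", "high")
  nris <- replicate(400, {
    g1 <- factor(sample(lv, 40, TRUE), levels = lv)
    g2 <- factor(sample(lv, 40, TRUE), levels = lv)
    labs <- c(rep(1, 15), rep(0, 25))
    nri(reclassification_table(g1, g2, labs))$overall_nri
  })
  expect_lt(abs(mean(nris)), 3 * sd(nris) / sqrt(length(nris)))
  expect_error(nri(reclass_table(matrix(0, 3, 3), diag(c(1, 1, 1)))),
               "undefined")
})

test_that("NRI Z-test matches a multinomial null simulation and handles zero movement", {
  # zero-movement table: undefined Z by the documented convention
  idt <- reclass_table(diag(c(4, 4, 4)), diag(c(8, 8, 8)))
  zt0 <- nri_z_test(idt)
  expect_true(is.na(zt0$z_event) && is.na(zt0$z_nonevent))
  # sign(z) equals sign of the component NRI on the packaged tables
  for (tb in reference_reclass_tables()) {
    zt <- nri_z_test(tb)
    r <- zt$nri
    if (!is.na(zt$z_event)) expect_equal(sign(zt$z_event), sign(r$event_nri))
    if (!is.na(zt$z_nonevent))
      expect_equal(sign(zt$z_nonevent), sign(r$nonevent_nri))
  }
  # parametric null: n subjects move up/down with equal probability p;
  # compare the analytic two-sided p with the simulated exceedance probability
  set.seed(209)
  n <- 200; p_move <- 0.15
  up_obs <- 38L; down_obs <- 22L
  ev <- matrix(0L, 3, 3); ev[1, 2] <- up_obs; ev[2, 1] <- down_obs
  ev[1, 1] <- n - up_obs - down_obs
  tb <- reclass_table(ev, diag(c(5, 5, 5)))
  zt <- nri_z_test(tb)
  nri_obs <- (up_obs - down_obs) / n
  sims <- replicate(50000, {
    mv <- rmultinom(1, n, c(p_move, p_move, 1 - 2 * p_move))
    (mv[1] - mv[2]) / n
  })
  p_sim <- mean(abs(sims) >= abs(nri_obs) - 1e-12)
  expect_lt(abs(zt$p_event - p_sim), 0.02)
})

test_that("toy scorer is deterministic, separates designed features, and favors follow-up patches", {
  ds <- generate_dataset(12, 24, seed = 301)
  labels <- as.integer(attr(ds, "labels") == "malignant")
  fus <- lapply(ds, `[[`, "followup")
  sc1 <- train_toy_scorer(fus, labels, seed = 1)
  sc2 <- train_toy_scorer(fus, labels, seed = 1)
  test_ds <- generate_dataset(10, 20, seed = 302)
  tl <- as.integer(attr(test_ds, "labels") == "malignant")
  s1 <- score_patches(sc1, lapply(test_ds, `[[`, "followup"), labels = tl)
  s2 <- score_patches(sc2, lapply(test_ds, `[[`, "followup"), labels = tl)
  expect_identical(s1$score, s2$score)
  expect_true(all(s1$score >= 0 & s1$score <= 1))
  auc_fu <- roc_auc(s1)$auc
  s_base <- score_patches(sc1, lapply(test_ds, `[[`, "baseline"), labels = tl)
  auc_base <- roc_auc(s_base)$auc
  # growth is the designed signal: follow-up patches separate at least as well
  expect_gte(auc_fu + 0.02, auc_base)
  expect_error(train_toy_scorer(fus, rep(1, length(fus))), "class")
})
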