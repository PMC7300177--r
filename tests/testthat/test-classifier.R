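# small labeled feature fixtures
toy_features <- function(n_pos = 8, n_neg = 16, n_noise = 5, seed = 1,
                         separator = TRUE) {
  set.seed(seed)
  n <- n_pos + n_neg
  labels <- factor(rep(c("less", "moderate"), c(n_pos, n_neg)),
                   levels = experience_levels())
  x <- matrix(rnorm(n * n_noise), n, n_noise,
              dimnames = list(NULL, paste0("noise", seq_len(n_noise))))
  if (separator) {
    sep <- ifelse(labels == "less", 1, -1) + 0.01 * rnorm(n)
    x <- cbind(sep = sep, x)
  }
  list(features = x, labels = labels, positive = labels == "less")
}

test_that("stratified folds satisfy the pigeonhole bounds deterministically", {
  labels <- rep(experience_levels(), times = c(24, 23, 31))
  f1 <- stratified_folds(labels, 10, seed = 5)
  f2 <- stratified_folds(labels, 10, seed = 5)
  expect_identical(f1, f2)
  expect_true(all(table(f1) %in% c(7, 8)))
  tab <- table(labels, f1)
  expect_true(all(tab["less", ] %in% c(2, 3)))
  expect_true(all(tab["moderate", ] %in% c(2, 3)))
  expect_true(all(tab["experienced", ] %in% c(3, 4)))
  expect_false(identical(f1, stratified_folds(labels, 10, seed = 6)))
  expect_error(stratified_folds(labels[1:5], 10), "more folds than subjects")
})

test_that("fold assignment is invariant to renaming the classes", {
  labels <- rep(c("less", "moderate", "experienced"), times = c(24, 23, 31))
  renamed <- c(less = "experienced", moderate = "less",
               experienced = "moderate")[labels]
  expect_identical(stratified_folds(labels, 10, seed = 2),
                   stratified_folds(renamed, 10, seed = 2))
})

test_that("cross-validation pools holdout predictions into one confusion matrix", {
  toy <- toy_features()
  folds <- stratified_folds(toy$labels, 4, seed = 1)
  cm <- cv_evaluate(toy$features, toy$positive, 1, folds)
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, length(toy$labels))
  expect_equal(cm$tp + cm$fn, sum(toy$positive))
  # near-perfect separator: no pooled errors
  expect_equal(cm$fp + cm$fn, 0)
  expect_error(cv_evaluate(toy$features[, 0], toy$positive, 1, folds), "empty")
})

test_that("a pure-noise feature classifies at the majority rate on average", {
  accs <- vapply(1:20, function(s) {
    set.seed(200 + s)
    labels <- factor(rep(c("less", "moderate"), c(8, 16)),
                     levels = experience_levels())
    x <- matrix(rnorm(24), 24, 1, dimnames = list(NULL, "noise1"))
    folds <- stratified_folds(labels, 4, seed = s)
    prf1(cv_evaluate(x, labels == "less", 1, folds))$accuracy
  }, numeric(1))
  expect_equal(mean(accs), 16 / 24, tolerance = 0.05)
})

test_that("a training fold with a single class predicts the majority and is flagged", {
  set.seed(2)
  labels <- factor(rep(c("less", "moderate"), c(1, 7)), levels = experience_levels())
  x <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("a", "b")))
  folds <- stratified_folds(labels, 8, seed = 1)
  cm <- cv_evaluate(x, labels == "less", 1, folds)
  expect_gte(length(attr(cm, "degenerate_folds")), 1)
  expect_equal(cm$tp, 0)  # the lone positive's training fold saw no positives
})

test_that("forward selection finds a dominant separator immediately", {
  toy <- toy_features(seed = 3)
  cand <- structure(list(features = toy$features, labels = toy$labels,
                         feature_names = colnames(toy$features)),
                    class = "candidate_set")
  rep <- forward_select(cand, "less",
                        selection_config(c_grid = 1, n_folds = 4, seed = 1))
  expect_equal(rep$selected_features[1], "sep")
  expect_equal(rep$metrics$mcc, 1)
  expect_equal(rep$confusion$fp + rep$confusion$fn, 0)
})

test_that("the greedy path matches an independently coded brute-force oracle", {
  set.seed(9)
  n <- 24
  labels <- factor(rep(c("less", "moderate"), each = 12),
                   levels = experience_levels())
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  x[, 2] <- x[, 2] + ifelse(labels == "less", 0.8, -0.8)
  x[, 4] <- x[, 4] + ifelse(labels == "less", 0.5, -0.5)
  folds <- stratified_folds(labels, 4, seed = 7)
  cfg <- selection_config(c_grid = 1, n_folds = 4, seed = 7,
                          max_features = 2, stall_patience = 99)
  cand <- structure(list(features = x, labels = labels,
                         feature_names = colnames(x)),
                    class = "candidate_set")
  rep <- forward_select(cand, "less", cfg, folds = folds)
  # oracle: exhaustive greedy over the same criterion
  crit <- function(feats) {
    cm <- cv_evaluate(x[, feats, drop = FALSE], labels == "less", 1, folds)
    c(mcc = mcc(cm), acc = prf1(cm)$accuracy)
  }
  step1 <- t(vapply(colnames(x), function(f) crit(f), numeric(2)))
  pick1 <- rownames(step1)[order(-step1[, "mcc"], -step1[, "acc"])][1]
  rest <- setdiff(colnames(x), pick1)
  step2 <- t(vapply(rest, function(f) crit(c(pick1, f)), numeric(2)))
  pick2 <- rownames(step2)[order(-step2[, "mcc"], -step2[, "acc"])][1]
  greedy_path <- c(pick1, pick2)
  best_prefix <- if (step2[pick2, "mcc"] > step1[pick1, "mcc"]) greedy_path else pick1
  expect_equal(rep$selected_features, best_prefix)
})

test_that("selection trace criterion is non-decreasing over the accepted prefix", {
  p <- small_prepared()
  rep <- forward_select(p$candidates, "less",
                        selection_config(c_grid = 1, n_folds = 4, seed = 2,
                                         max_features = 5))
  crit <- vapply(rep$selection_trace, function(s) s$criterion, numeric(1))
  crit <- crit[!is.na(crit)]
  expect_true(all(diff(crit) >= 0))
  # confusion marginals match the class sizes exactly
  expect_equal(rep$confusion$tp + rep$confusion$fn, sum(p$labels == "less"))
  expect_equal(rep$confusion$fp + rep$confusion$tn, sum(p$labels != "less"))
})

test_that("fit_all_classes returns three reports symmetric under relabeling", {
  p <- small_prepared()
  cfg <- selection_config(c_grid = 1, n_folds = 4, seed = 3, max_features = 3)
  reports <- fit_all_classes(p$candidates, cfg)
  expect_named(reports, experience_levels())
  for (r in reports) expect_s3_class(r, "one_vs_all_report")
  # permute the class names: reports permute, per-class metrics identical
  perm <- c(less = "experienced", moderate = "less", experienced = "moderate")
  cand2 <- p$candidates
  cand2$labels <- factor(perm[as.character(p$candidates$labels)],
                         levels = experience_levels())
  reports2 <- fit_all_classes(cand2, cfg)
  for (cl in experience_levels())
    expect_equal(reports2[[perm[[cl]]]]$metrics, reports[[cl]]$metrics)
})

test_that("increasing the planted offset cannot reduce recovery MCC", {
  mccs <- vapply(c(0.5, 3, 6), function(off) {
    co <- generate_cohort(cohort_config(group_sizes = c(8, 8, 8),
                                        met_hal_offset_deg = off,
                                        cal_met_offset_deg = 0.8 * off,
                                        seed = 31))
    sets <- preprocess_cohort(co)
    wm <- assemble_matrix(sets)
    pca <- fit_waveform_pca(wm)
    cand <- build_candidates(pca, grf_table(co),
                             stats::setNames(co$metadata$group,
                                             co$metadata$subject_id))
    rep <- forward_select(cand, "less",
                          selection_config(c_grid = 1, n_folds = 4, seed = 5,
                                           max_features = 3))
    rep$metrics$mcc
  }, numeric(1))
  expect_gte(mccs[2], mccs[1] - 0.15)
  expect_gte(mccs[3], mccs[2] - 0.15)
  expect_gte(mccs[3], mccs[1])
})
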