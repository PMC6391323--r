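test_that("split_dataset stratifies with floor + largest-remainder counts", {
  x <- noise_table(nf = 5, n1 = 10, n2 = 10, seed = 1)
  sp <- split_dataset(x, c(0.6, 0.2, 0.2), seed = 4)
  for (part in sp) {
    expect_s3_class(part, "PeakTable")
  }
  counts <- sapply(sp, function(p) c(sum(p$groups == "case"),
                                     sum(p$groups == "control")))
  expect_equal(unname(counts), matrix(c(6, 6, 2, 2, 2, 2), nrow = 2))
  # no sample lost or duplicated
  ids <- unlist(lapply(sp, `[[`, "sample_ids"))
  expect_setequal(ids, x$sample_ids)

  all_train <- split_dataset(x, c(1, 0, 0), seed = 1)
  expect_equal(n_samples(all_train$train), 20L)
  expect_null(all_train$test)
  expect_null(all_train$independent)

  expect_identical(split_dataset(x, seed = 9), split_dataset(x, seed = 9))
  expect_false(identical(split_dataset(x, seed = 9)$train$sample_ids,
                         split_dataset(x, seed = 10)$train$sample_ids))
})

test_that("confusion metrics follow their closed forms", {
  perfect <- confusion_metrics(10, 10, 0, 0)
  expect_equal(unlist(perfect[c("sen", "spe", "acc", "mcc")]),
               c(sen = 1, spe = 1, acc = 1, mcc = 1))
  m <- confusion_metrics(8, 9, 1, 2)
  expect_equal(m$sen, 0.8)
  expect_equal(m$spe, 0.9)
  expect_equal(m$acc, 0.85)
  expect_equal(m$mcc, 70 / sqrt(9900))
  # zero denominator -> NA, flagged, never silently 0
  und <- confusion_metrics(0, 5, 0, 0)
  expect_true(is.na(und$sen))
  expect_true("sen" %in% und$undefined)
})

test_that("ACC is the prevalence-weighted combination of SEN and SPE", {
  set.seed(7)
  for (i in 1:20) {
    cts <- rmultinom(1, 60, c(0.3, 0.3, 0.2, 0.2)) + 1L
    m <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    npos <- cts[1] + cts[4]
    nneg <- cts[2] + cts[3]
    expect_equal(m$acc, (npos * m$sen + nneg * m$spe) / (npos + nneg))
  }
})

test_that("rank AUC hits its bounds, handles ties, and is monotone-invariant", {
  labels <- rep(c("case", "control"), each = 5)
  expect_equal(roc_auc(c(rep(1, 5), rep(0, 5)), labels), 1)
  expect_equal(roc_auc(c(rep(0, 5), rep(1, 5)), labels), 0)
  expect_equal(roc_auc(rep(2, 10), labels), 0.5)  # all tied -> 1/2 per tie
  set.seed(1)
  s <- rnorm(10)
  expect_equal(roc_auc(exp(3 * s) + 2, labels), roc_auc(s, labels))
  expect_error(roc_auc(1:3, rep("case", 3)), "both classes")
})

test_that("null scores on balanced labels give AUC ~ 0.5", {
  set.seed(42)
  labels <- rep(c("case", "control"), each = 5000)
  auc <- roc_auc(rnorm(10000), labels)
  expect_lt(abs(auc - 0.5), 0.02)
})

test_that("strong planted markers yield >= 0.9 independent-test accuracy", {
  for (seed in c(2, 14)) {
    pair <- generate_pair(synthetic_config(
      n_features_shared = 150, n_features_unique_per_exp = 0,
      n_case = 50, n_control = 50, n_true_markers = 10, effect_size = 3,
      missing_rate = 0, seed = seed))
    pre <- pretreat(pair$exp1)
    sp <- split_dataset(pre, c(0.6, 0.2, 0.2), seed = seed)
    cm <- fit_and_evaluate(sp$train, sp$test, sp$independent)
    expect_gte(cm$acc, 0.9)
    expect_gte(cm$auc, 0.9)
  }
})

test_that("null data gives chance-level AUC on the independent split", {
  aucs <- sapply(1:20, function(seed) {
    x <- noise_table(nf = 80, n1 = 25, n2 = 25, seed = seed + 100)
    sp <- split_dataset(x, c(0.6, 0.2, 0.2), seed = seed)
    suppressWarnings(fit_and_evaluate(sp$train, sp$test, sp$independent))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("the independent split never influences selection or fitting", {
  pair <- generate_pair(synthetic_config(
    n_features_shared = 100, n_features_unique_per_exp = 0,
    n_case = 30, n_control = 30, n_true_markers = 8, effect_size = 2,
    missing_rate = 0, seed = 8))
  pre <- pretreat(pair$exp1)
  sp <- split_dataset(pre, c(0.6, 0.2, 0.2), seed = 3)
  cm1 <- fit_and_evaluate(sp$train, sp$test, sp$independent)
  flipped <- sp$independent
  flipped$groups <- rev(flipped$groups)
  cm2 <- fit_and_evaluate(sp$train, sp$test, flipped)
  expect_identical(cm2$n_features_selected, cm1$n_features_selected)
  expect_identical(cm2$hyperparameters, cm1$hyperparameters)
  expect_false(identical(cm1$counts, cm2$counts))
})

test_that("duplicating samples preserves the |t| ranking of features", {
  x <- noise_table(nf = 40, n1 = 8, n2 = 8, effect = 1, n_true = 10, seed = 5)
  dup <- x
  dup$intensities <- cbind(x$intensities, x$intensities)
  dup$sample_ids <- c(x$sample_ids, paste0(x$sample_ids, "b"))
  dup$groups <- c(x$groups, x$groups)
  dup$experiment <- c(x$experiment, x$experiment)
  t1 <- row_ttest(x)$t
  t2 <- row_ttest(dup)$t
  expect_identical(order(-abs(t1)), order(-abs(t2)))
  # t scales by a constant factor, so matched-threshold selection is equal
  expect_equal(t2 / t1, rep(t2[1] / t1[1], 40), tolerance = 1e-8)
})

test_that("RBF-SVM separates separable data and stays deterministic", {
  set.seed(9)
  X <- rbind(matrix(rnorm(40, 2), 20, 2), matrix(rnorm(40, -2), 20, 2))
  y <- rep(c(1, -1), each = 20)
  m1 <- metastrat:::svm_rbf_fit(X, y, cost = 10, gamma = 0.5)
  m2 <- metastrat:::svm_rbf_fit(X, y, cost = 10, gamma = 0.5)
  expect_identical(m1, m2)
  expect_equal(mean(sign(metastrat:::svm_rbf_decision(m1, X)) == y), 1)
})
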