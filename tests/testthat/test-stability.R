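test_that("half_sample draws floor(n/2) per group, reproducibly", {
  x <- noise_table(nf = 5, n1 = 20, n2 = 24, seed = 1)
  h <- half_sample(x, seed = 2)
  expect_equal(sum(h$groups == "case"), 10L)
  expect_equal(sum(h$groups == "control"), 12L)
  x59 <- noise_table(nf = 5, n1 = 59, n2 = 10, seed = 1)
  expect_equal(sum(half_sample(x59, seed = 1)$groups == "case"), 29L)
  expect_identical(half_sample(x, seed = 7)$sample_ids,
                   half_sample(x, seed = 7)$sample_ids)
  small <- noise_table(nf = 5, n1 = 3, n2 = 8, seed = 1)
  expect_error(half_sample(small), ">= 4")
})

test_that("overlap follows its closed form and conventions", {
  a <- sprintf("m%02d", 1:3)
  b <- c("m01", "m02", "x1", "x2")
  expect_equal(overlap(a, b), 4 / 7)
  expect_equal(overlap(a, a), 1)
  expect_equal(overlap(a, c("y1", "y2")), 0)
  expect_equal(overlap(character(0), character(0)), 0)
})

test_that("property: overlap is symmetric, bounded, 1 iff set-equal", {
  set.seed(3)
  for (i in 1:20) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(0:15, 1))
    o <- overlap(a, b)
    expect_equal(o, overlap(b, a))
    expect_gte(o, 0)
    expect_lte(o, 1)
    if (length(a) || length(b)) {
      expect_equal(o == 1, setequal(a, b))
    }
  }
})

test_that("robustness_report yields choose(n,2) overlaps and a coherent profile", {
  x <- noise_table(nf = 60, n1 = 12, n2 = 12, effect = 1.5, n_true = 10,
                   seed = 21)
  rep10 <- robustness_report(x, n_iter = 10, seed = 5)
  expect_length(rep10$overlaps, 45L)
  expect_length(rep10$marker_counts, 10L)
  expect_true(all(rep10$overlaps >= 0 & rep10$overlaps <= 1))
  # co-identification counts grow as the threshold relaxes, capped by union
  expect_true(all(diff(rep10$coidentification$count) >= 0))
  expect_lte(max(rep10$coidentification$count), rep10$total_identified)
  expect_identical(rep10$coidentification$threshold[1], "N=10")
  # determinism from the master seed
  expect_equal(robustness_report(x, n_iter = 10, seed = 5)$overlaps,
               rep10$overlaps)
})

test_that("a saturated table gives all-1 overlaps and median 1", {
  x <- saturated_table()
  rep <- robustness_report(x, n_iter = 10, seed = 2)
  expect_equal(rep$overlaps, rep(1, 45))
  expect_equal(rep$median_overlap, 1)
  expect_equal(rep$coidentification$count[1], n_features(x))
  expect_equal(rep$coidentification$percent[1], 100)
})

test_that("overlap-distribution comparison behaves at its extremes", {
  x <- rep(0.9, 45)
  y <- rep(0.1, 45)
  expect_lt(as.numeric(compare_overlap_distributions(x, y)), 1e-10)
  expect_gt(as.numeric(compare_overlap_distributions(y, x)), 0.999)
  set.seed(1)
  z <- runif(45)
  expect_gte(as.numeric(compare_overlap_distributions(z, z)), 0.5)
  tied <- compare_overlap_distributions(rep(0.3, 5), rep(0.3, 7))
  expect_equal(as.numeric(tied), 1)
  expect_true(attr(tied, "degenerate"))
})

test_that("enrichment factor reproduces the published worked examples", {
  expect_equal(round(enrichment_factor(4, 2523, 7, 34840), 2), 7.89)
  expect_equal(round(enrichment_factor(5, 9709, 9, 42269), 2), 2.42)
  expect_equal(round(enrichment_factor(5, 1862, 11, 19724), 2), 4.81)
  # identified = whole universe -> exactly random
  expect_equal(enrichment_factor(7, 34840, 7, 34840), 1)
  # invariant to common scaling of all counts
  expect_equal(enrichment_factor(8, 400, 14, 7000),
               enrichment_factor(8 * 3, 400 * 3, 14 * 3, 7000 * 3))
  expect_error(enrichment_factor(1, 0, 1, 10), "zero denominator")
  expect_error(enrichment_factor(5, 4, 1, 10), "cannot exceed")
})

test_that("ef_report counts match direct set arithmetic", {
  pair <- small_pair(seed = 23)
  pre <- pretreat(pair$exp1)
  ann <- annotate(pre, pair$library, tol_ppm = 20)
  truth <- pair$truth$true_metabolite_ids

  # markers = all features -> identified set == universe -> EF = 1
  all_markers <- row_ttest(pre)$feature_key
  ef_all <- ef_report(all_markers, ann, truth)
  expect_equal(ef_all$ef, 1)
  expect_equal(ef_all$n_identified_annotated, ef_all$n_detected_annotated)

  # markers = exactly the features annotating to true markers -> maximal EF
  hits <- names(Filter(function(ids) any(ids %in% truth), ann$mapping))
  ef_max <- ef_report(hits, ann, truth)
  expect_equal(ef_max$n_true_identified, ef_max$n_true_detected)
  expect_equal(ef_max$ef,
               ef_max$n_detected_annotated / ef_max$n_identified_annotated)

  # truth disjoint from the universe -> EF undefined and flagged
  ef_bad <- ef_report(all_markers, ann, c("nope1", "nope2"))
  expect_true(ef_bad$ef_undefined)
  expect_true(is.na(ef_bad$ef))
})
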