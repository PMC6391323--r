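test_that("run configuration validates and round-trips through YAML", {
  cfg <- run_config(seed = 3, tol_value = 0.1, tol_unit = "ppm", n_iter = 8)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2, cfg)
  expect_error(run_config(split = c(0.5, 0.5)), "3 fractions")
  expect_error(run_config(alpha = 2), "alpha")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("bogus_key: 1", f2)
  expect_error(read_run_config(f2), "unknown config key")
})

test_that("ReIn on two identical experiments reduces exactly to SiE", {
  pair <- small_pair(seed = 41)
  cfg <- run_config(seed = 11)
  a <- pair$exp1
  b <- a
  b$sample_ids <- paste0("dup_", a$sample_ids)
  sie <- run_sie(a, cfg, pair$library, pair$truth$true_metabolite_ids)
  rein <- run_rein(a, b, cfg, pair$library, pair$truth$true_metabolite_ids)
  expect_equal(rein$classification$acc, sie$classification$acc)
  expect_equal(rein$classification$auc, sie$classification$auc)
  expect_equal(rein$robustness$overlaps, sie$robustness$overlaps)
  expect_equal(rein$robustness$median_overlap, sie$robustness$median_overlap)
  expect_equal(rein$ef$ef, sie$ef$ef)
  expect_equal(rein$ef$n_identified_annotated, sie$ef$n_identified_annotated)
})

test_that("ReIn integrates by averaging metrics and intersecting metabolites", {
  pair <- small_pair(seed = 43)
  cfg <- run_config(seed = 17)
  truth <- pair$truth$true_metabolite_ids
  rein <- run_rein(pair$exp1, pair$exp2, cfg, pair$library, truth)
  r1 <- rein$components$exp1
  r2 <- rein$components$exp2
  expect_equal(rein$classification$acc,
               mean(c(r1$classification$acc, r2$classification$acc)))
  expect_equal(rein$robustness$overlaps,
               (r1$robustness$overlaps + r2$robustness$overlaps) / 2)
  expect_lte(rein$ef$n_identified_annotated,
             min(r1$ef$n_identified_annotated, r2$ef$n_identified_annotated))
  expect_identical(sort(rein$ef$identified_ids),
                   sort(intersect(r1$ef$identified_ids, r2$ef$identified_ids)))
})

test_that("self-merged DiMe markers form a superset of the SiE marker set", {
  pair <- small_pair(seed = 47)
  a <- pair$exp1
  b <- a
  b$sample_ids <- paste0("dup_", a$sample_ids)
  b$experiment <- rep("exp2", n_samples(b))
  merged <- merge_tables(a, b)
  sie_markers <- marker_ids(ttest_markers(pretreat(a)))
  dime_markers <- marker_ids(ttest_markers(pretreat(merged)))
  expect_true(all(sie_markers %in% dime_markers))
  expect_equal(n_samples(merged), 2L * n_samples(a))
})

test_that("DiMe bookkeeping: merged sizes and report fields", {
  pair <- small_pair(seed = 53)
  cfg <- run_config(seed = 5)
  rep <- run_dime(pair$exp1, pair$exp2, cfg, pair$library,
                  pair$truth$true_metabolite_ids)
  expect_equal(rep$n_samples, n_samples(pair$exp1) + n_samples(pair$exp2))
  expect_lte(rep$n_features, min(n_features(pair$exp1), n_features(pair$exp2)))
  expect_equal(rep$match$n_matched, rep$n_features)
  expect_s3_class(rep$classification, "ClassificationMetrics")
  expect_s3_class(rep$robustness, "OverlapReport")
  expect_s3_class(rep$ef, "EFReport")
})

test_that("compare_strategies emits four deterministic reports with provenance", {
  pair <- small_pair(seed = 59)
  cfg <- run_config(seed = 23)
  truth <- pair$truth$true_metabolite_ids
  cmp <- compare_strategies(pair$exp1, pair$exp2, cfg, pair$library, truth)
  expect_named(cmp$reports, c("SiE1", "SiE2", "ReIn", "DiMe"))
  expect_equal(nrow(cmp$classification_table), 4L)
  expect_length(cmp$overlap_tests, 3L)
  for (r in cmp$reports) {
    expect_identical(r$provenance$config$seed, cfg$seed)
    expect_false(is.null(r$provenance$seeds$robustness))
  }
  cmp2 <- compare_strategies(pair$exp1, pair$exp2, cfg, pair$library, truth)
  expect_equal(cmp$classification_table, cmp2$classification_table)
  expect_equal(cmp$robustness_table, cmp2$robustness_table)
  expect_equal(cmp$ef_table, cmp2$ef_table)
})

test_that("write_comparison produces a parseable JSON report and CSV tables", {
  pair <- small_pair(seed = 61)
  cfg <- run_config(seed = 2)
  cmp <- compare_strategies(pair$exp1, pair$exp2, cfg, pair$library,
                            pair$truth$true_metabolite_ids)
  dir <- withr::local_tempdir()
  paths <- write_comparison(cmp, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  payload <- jsonlite::read_json(file.path(dir, "report.json"),
                                 simplifyVector = TRUE)
  expect_named(payload$strategies, c("SiE1", "SiE2", "ReIn", "DiMe"))
  expect_equal(payload$strategies$DiMe$robustness$median_overlap,
               cmp$reports$DiMe$robustness$median_overlap)
  tab <- read.csv(file.path(dir, "classification.csv"))
  expect_equal(tab$strategy, c("SiE1", "SiE2", "ReIn", "DiMe"))
})

test_that("the command-line interface runs the simulate and merge commands", {
  cli <- file.path(system.file(package = "metastrat"), "exec", "metastrat")
  if (!file.exists(cli)) {
    cli <- file.path(find.package("metastrat"), "exec", "metastrat")
  }
  expect_true(file.exists(cli))
  dir <- withr::local_tempdir()
  cfgf <- file.path(dir, "syn.yaml")
  yaml::write_yaml(list(n_features_shared = 60, n_features_unique_per_exp = 20,
                        n_case = 8, n_control = 8, decoy_rate = 2, seed = 4),
                   cfgf)
  out1 <- system2("Rscript", c(cli, "simulate", "--config", cfgf,
                               "--out", dir), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "exp1.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  merged <- file.path(dir, "merged.csv")
  system2("Rscript", c(cli, "merge", "--a", file.path(dir, "exp1.csv"),
                       "--b", file.path(dir, "exp2.csv"),
                       "--meta-a", file.path(dir, "exp1_meta.csv"),
                       "--meta-b", file.path(dir, "exp2_meta.csv"),
                       "--tol", "0.05", "--tol-unit", "Da",
                       "--out", merged), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(merged))
  m <- read_peak_table(merged, paste0(merged, ".meta.csv"))
  expect_equal(n_features(m), 60L)
  expect_equal(n_samples(m), 32L)
})
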