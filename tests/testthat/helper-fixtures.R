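# Small in-code fixtures shared across the suite.

# A tiny fully observed 3-feature x 4-sample table.
tiny_table <- function() {
  peak_table(
    mz = c(100.05, 200.10, 300.15),
    rt = c(60, 120, 180),
    intensities = matrix(c(2, 4, 6,
                           1, 2, 3,
                           4, 8, 12,
                           3, 6, 9), nrow = 3),
    sample_ids = paste0("s", 1:4),
    groups = c("case", "case", "control", "control")
  )
}

# Random complete table: nf features, n1 cases + n2 controls, pure noise on
# the log scale unless `effect` shifts the first `n_true` features in cases.
noise_table <- function(nf = 50, n1 = 10, n2 = 10, effect = 0, n_true = 0,
                        seed = 1) {
  set.seed(seed)
  ns <- n1 + n2
  groups <- rep(c("case", "control"), c(n1, n2))
  M <- exp(matrix(rnorm(nf * ns, 8, 0.5), nf, ns))
  if (n_true > 0 && effect != 0) {
    M[seq_len(n_true), groups == "case"] <-
      M[seq_len(n_true), groups == "case"] * exp(effect * 0.5)
  }
  peak_table(seq(100, by = 1.3, length.out = nf),
             seq(30, by = 5, length.out = nf),
             M, sprintf("s%03d", seq_len(ns)), groups)
}

# A table whose marker list is identical for every half-sample: all
# features carry an enormous case/control separation.
saturated_table <- function(nf = 8, n1 = 10, n2 = 12, seed = 3) {
  set.seed(seed)
  groups <- rep(c("case", "control"), c(n1, n2))
  M <- exp(matrix(rnorm(nf * (n1 + n2), 8, 0.2), nf, n1 + n2) +
             outer(rep(20, nf), as.numeric(groups == "case")))
  peak_table(seq(100, by = 2, length.out = nf),
             seq(60, by = 10, length.out = nf),
             M, sprintf("s%02d", seq_len(n1 + n2)), groups)
}

# Small synthetic pair used by several integration tests.
small_pair <- function(seed = 11, ...) {
  generate_pair(synthetic_config(
    n_features_shared = 150, n_features_unique_per_exp = 60,
    n_true_markers = 12, missing_rate = 0.15, decoy_rate = 10,
    seed = seed, ...))
}

expect_same_report <- function(r1, r2) {
  expect_equal(r1$classification$acc, r2$classification$acc)
  expect_equal(r1$classification$auc, r2$classification$auc)
  expect_equal(r1$robustness$overlaps, r2$robustness$overlaps)
  expect_equal(r1$ef$ef, r2$ef$ef)
}
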