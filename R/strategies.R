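#' Run configuration for the strategy comparison
#'
#' Bundles every threshold of the analysis pipeline under one master seed.
#' Stage seeds (splitting, robustness) are derived deterministically from
#' the master seed, so each stage is individually reproducible and a report
#' can be re-run bit-identically.
#'
#' @param tol_value,tol_unit feature-matching m/z tolerance for the merge
#'   (default 0.05 Da; `"ppm"` reproduces the relative variant).
#' @param k,min_overlap KNN imputation parameters.
#' @param alpha significance threshold used throughout.
#' @param vip_threshold,n_components PLS-DA marker-calling parameters.
#' @param annotation_ppm,ion_mode metabolite annotation window and adduct
#'   mode.
#' @param split train/test/independent fractions.
#' @param n_iter robustness half-samplings.
#' @param seed master seed.
#' @return a `RunConfig` list.
#' @export
run_config <- function(tol_value = 0.05, tol_unit = "Da",
                       k = 10L, min_overlap = 3L,
                       alpha = 0.05,
                       vip_threshold = 1, n_components = 2L,
                       annotation_ppm = 20, ion_mode = "positive",
                       split = c(0.6, 0.2, 0.2),
                       n_iter = 10L,
                       seed = 1L) {
  cfg <- list(tol = mz_tolerance(tol_value, tol_unit),
              k = as.integer(k), min_overlap = as.integer(min_overlap),
              alpha = alpha,
              vip_threshold = vip_threshold,
              n_components = as.integer(n_components),
              annotation_ppm = annotation_ppm,
              ion_mode = match.arg(ion_mode, c("positive", "negative")),
              split = split,
              n_iter = as.integer(n_iter),
              seed = as.integer(seed))
  if (cfg$alpha < 0 || cfg$alpha > 1) stop("alpha must be in [0, 1]")
  if (length(cfg$split) != 3L || abs(sum(cfg$split) - 1) > 1e-8) {
    stop("split must be 3 fractions summing to 1")
  }
  if (cfg$n_iter < 2L) stop("n_iter must be >= 2")
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Accepts a YAML mapping whose keys are the arguments of [run_config()];
#' absent keys take the defaults.
#'
#' @param path YAML file.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key '", unknown[1], "'")
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#' @param cfg a `RunConfig`.
#' @param path output file.
#' @return `cfg`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "RunConfig"))
  yaml::write_yaml(list(
    tol_value = cfg$tol$value, tol_unit = cfg$tol$unit,
    k = cfg$k, min_overlap = cfg$min_overlap, alpha = cfg$alpha,
    vip_threshold = cfg$vip_threshold, n_components = cfg$n_components,
    annotation_ppm = cfg$annotation_ppm, ion_mode = cfg$ion_mode,
    split = cfg$split, n_iter = cfg$n_iter, seed = cfg$seed
  ), path)
  invisible(cfg)
}

# Deterministic seed fan-out from the master seed (kept below 2^31).
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 48271 + offset * 16807) %% 2147483647L) + 1L
}

strategy_provenance <- function(strategy, cfg) {
  list(strategy = strategy,
       config = list(tol = unclass(cfg$tol), k = cfg$k,
                     min_overlap = cfg$min_overlap, alpha = cfg$alpha,
                     vip_threshold = cfg$vip_threshold,
                     n_components = cfg$n_components,
                     annotation_ppm = cfg$annotation_ppm,
                     ion_mode = cfg$ion_mode, split = cfg$split,
                     n_iter = cfg$n_iter, seed = cfg$seed),
       seeds = list(split = derive_seed(cfg$seed, 1L),
                    robustness = derive_seed(cfg$seed, 2L)),
       package_version = as.character(utils::packageVersion("metastrat")))
}

criteria_on_table <- function(pre, strategy, cfg, lib, truth) {
  splits <- split_dataset(pre, cfg$split, seed = derive_seed(cfg$seed, 1L))
  classification <- fit_and_evaluate(splits$train, splits$test,
                                     splits$independent, alpha = cfg$alpha)
  robustness <- robustness_report(pre, n_iter = cfg$n_iter,
                                  alpha = cfg$alpha,
                                  seed = derive_seed(cfg$seed, 2L))
  markers <- plsda_markers(pre, vip_threshold = cfg$vip_threshold,
                           alpha = cfg$alpha,
                           n_components = cfg$n_components)
  ann <- annotate(pre, lib, tol_ppm = cfg$annotation_ppm, mode = cfg$ion_mode)
  ef <- ef_report(markers, ann, truth)
  structure(list(strategy = strategy,
                 classification = classification,
                 robustness = robustness,
                 ef = ef,
                 n_markers = nrow(markers),
                 n_features = n_features(pre),
                 n_samples = n_samples(pre),
                 provenance = strategy_provenance(strategy, cfg)),
            class = "StrategyReport")
}

#' Single-experiment (SiE) strategy
#'
#' Pretreats one experiment's peak table (KNN imputation then MSTUS) and
#' scores it under all three criteria: SVM classification on stratified
#' splits, half-sampling robustness, and PLS-DA marker identification with
#' ppm annotation feeding the enrichment factor.
#'
#' @param exp a raw `PeakTable` (one experiment).
#' @param cfg a [run_config()].
#' @param lib a `ReferenceLibrary`.
#' @param truth a `TrueMarkerSet`.
#' @param strategy report label (`"SiE1"` / `"SiE2"`).
#' @return a `StrategyReport`.
#' @export
run_sie <- function(exp, cfg, lib, truth, strategy = "SiE1") {
  pre <- pretreat(exp, k = cfg$k, min_overlap = cfg$min_overlap)
  criteria_on_table(pre, strategy, cfg, lib, truth)
}

#' Direct data-merging (DiMe) strategy
#'
#' Matches the two experiments' features by m/z, merges the tables over the
#' common features (concatenating all samples), pretreats the merged table,
#' and scores it under the three criteria.
#'
#' @inheritParams run_sie
#' @param a,b the two raw `PeakTable`s.
#' @return a `StrategyReport` (with `n_features` = merged common features).
#' @export
run_dime <- function(a, b, cfg, lib, truth) {
  ms <- match_features(a, b, cfg$tol)
  merged <- merge_tables(a, b, ms)
  pre <- pretreat(merged, k = cfg$k, min_overlap = cfg$min_overlap)
  rep <- criteria_on_table(pre, "DiMe", cfg, lib, truth)
  rep$match <- list(n_matched = nrow(ms$pairs),
                    n_unmatched_a = length(ms$unmatched_a),
                    n_unmatched_b = length(ms$unmatched_b))
  rep
}

mean_or_na <- function(u, v) {
  if (is.na(u) || is.na(v)) NA_real_ else (u + v) / 2
}

#' Results-integration (ReIn) strategy
#'
#' Runs the full single-experiment pipeline on each experiment, then
#' integrates: classification metrics are averaged over the two
#' experiments; robustness overlaps are averaged pairwise (iteration pair
#' by iteration pair) and per-iteration marker counts averaged; for the
#' enrichment factor, the detected universe is the intersection of the two
#' annotated universes and the identified set the intersection of the two
#' identified metabolite sets. On two identical experiments ReIn reduces
#' exactly to SiE.
#'
#' @inheritParams run_dime
#' @return a `StrategyReport` carrying the two per-experiment reports in
#'   `$components`.
#' @export
run_rein <- function(a, b, cfg, lib, truth) {
  r1 <- run_sie(a, cfg, lib, truth, strategy = "SiE1")
  r2 <- run_sie(b, cfg, lib, truth, strategy = "SiE2")

  cls <- structure(list(
    sen = mean_or_na(r1$classification$sen, r2$classification$sen),
    spe = mean_or_na(r1$classification$spe, r2$classification$spe),
    acc = mean_or_na(r1$classification$acc, r2$classification$acc),
    mcc = mean_or_na(r1$classification$mcc, r2$classification$mcc),
    auc = mean_or_na(r1$classification$auc, r2$classification$auc),
    counts = r1$classification$counts + r2$classification$counts,
    undefined = union(r1$classification$undefined, r2$classification$undefined)
  ), class = "ClassificationMetrics")

  o1 <- r1$robustness; o2 <- r2$robustness
  coident <- o1$coidentification
  coident$count <- (o1$coidentification$count + o2$coidentification$count) / 2
  coident$percent <- (o1$coidentification$percent + o2$coidentification$percent) / 2
  rob <- structure(list(
    n_iterations = o1$n_iterations,
    marker_counts = (o1$marker_counts + o2$marker_counts) / 2,
    marker_lists = NULL,
    overlaps = (o1$overlaps + o2$overlaps) / 2,
    median_overlap = stats::median((o1$overlaps + o2$overlaps) / 2),
    total_identified = (o1$total_identified + o2$total_identified) / 2,
    coidentification = coident,
    alpha = o1$alpha, seed = o1$seed
  ), class = "OverlapReport")

  ef <- ef_from_sets(
    identified = intersect(r1$ef$identified_ids, r2$ef$identified_ids),
    universe = intersect(r1$ef$universe_ids, r2$ef$universe_ids),
    truth = truth
  )

  structure(list(strategy = "ReIn",
                 classification = cls,
                 robustness = rob,
                 ef = ef,
                 n_markers = (r1$n_markers + r2$n_markers) / 2,
                 n_features = c(r1$n_features, r2$n_features),
                 n_samples = r1$n_samples + r2$n_samples,
                 components = list(exp1 = r1, exp2 = r2),
                 provenance = strategy_provenance("ReIn", cfg)),
            class = "StrategyReport")
}

#' @export
print.StrategyReport <- function(x, ...) {
  cat("StrategyReport [", x$strategy, "]\n", sep = "")
  print(x$classification)
  cat(sprintf("  robustness: median overlap %.3f over %d pairs\n",
              x$robustness$median_overlap, length(x$robustness$overlaps)))
  if (x$ef$ef_undefined) cat("  EF: undefined\n")
  else cat(sprintf("  EF: %.2f\n", x$ef$ef))
  invisible(x)
}

#' Compare the four analytical strategies on a pair of experiments
#'
#' Runs SiE1, SiE2, ReIn and DiMe with a shared configuration and seed, and
#' assembles side-by-side summary tables for the three criteria plus
#' one-sided rank-sum p-values testing whether the DiMe overlap
#' distribution is stochastically higher than each other strategy's.
#'
#' @inheritParams run_dime
#' @return a `StrategyComparison` list: `reports` (the four
#'   `StrategyReport`s), `classification_table`, `robustness_table`,
#'   `ef_table`, and `overlap_tests`.
#' @export
compare_strategies <- function(a, b, cfg, lib, truth) {
  rein <- run_rein(a, b, cfg, lib, truth)
  reports <- list(SiE1 = rein$components$exp1,
                  SiE2 = rein$components$exp2,
                  ReIn = rein,
                  DiMe = run_dime(a, b, cfg, lib, truth))

  classification_table <- do.call(rbind, lapply(reports, function(r) {
    data.frame(strategy = r$strategy,
               ACC = r$classification$acc, SEN = r$classification$sen,
               SPE = r$classification$spe, MCC = r$classification$mcc,
               AUC = r$classification$auc, stringsAsFactors = FALSE)
  }))
  robustness_table <- do.call(rbind, lapply(reports, function(r) {
    data.frame(strategy = r$strategy,
               median_overlap = r$robustness$median_overlap,
               total_markers = r$robustness$total_identified,
               stringsAsFactors = FALSE)
  }))
  ef_table <- do.call(rbind, lapply(reports, function(r) {
    data.frame(strategy = r$strategy,
               n_detected_annotated = r$ef$n_detected_annotated,
               n_true_detected = r$ef$n_true_detected,
               n_identified_annotated = r$ef$n_identified_annotated,
               n_true_identified = r$ef$n_true_identified,
               ef = r$ef$ef, stringsAsFactors = FALSE)
  }))
  rownames(classification_table) <- rownames(robustness_table) <-
    rownames(ef_table) <- NULL

  dime_ov <- reports$DiMe$robustness$overlaps
  overlap_tests <- vapply(c("SiE1", "SiE2", "ReIn"), function(s) {
    as.numeric(compare_overlap_distributions(dime_ov,
                                             reports[[s]]$robustness$overlaps))
  }, numeric(1))

  structure(list(reports = reports,
                 classification_table = classification_table,
                 robustness_table = robustness_table,
                 ef_table = ef_table,
                 overlap_tests = overlap_tests,
                 config = cfg),
            class = "StrategyComparison")
}

#' @export
print.StrategyComparison <- function(x, ...) {
  cat("Strategy comparison (seed", x$config$seed, ")\n\nClassification:\n")
  print(x$classification_table, digits = 3)
  cat("\nRobustness:\n")
  print(x$robustness_table, digits = 3)
  cat("\nEnrichment factor:\n")
  print(x$ef_table, digits = 3)
  cat("\nDiMe-vs-other one-sided rank-sum p-values on overlaps:\n")
  print(signif(x$overlap_tests, 3))
  invisible(x)
}

report_to_list <- function(r) {
  list(strategy = r$strategy,
       classification = list(sen = r$classification$sen,
                             spe = r$classification$spe,
                             acc = r$classification$acc,
                             mcc = r$classification$mcc,
                             auc = r$classification$auc,
                             counts = as.list(r$classification$counts)),
       robustness = list(n_iterations = r$robustness$n_iterations,
                         marker_counts = r$robustness$marker_counts,
                         overlaps = r$robustness$overlaps,
                         median_overlap = r$robustness$median_overlap,
                         total_identified = r$robustness$total_identified,
                         coidentification = r$robustness$coidentification),
       ef = list(n_detected_annotated = r$ef$n_detected_annotated,
                 n_true_detected = r$ef$n_true_detected,
                 n_identified_annotated = r$ef$n_identified_annotated,
                 n_true_identified = r$ef$n_true_identified,
                 ef = r$ef$ef, low_support = r$ef$low_support),
       provenance = r$provenance)
}

#' Write a strategy comparison to disk
#'
#' Emits `report.json` (all four strategies, overlap tests, provenance),
#' CSV summary tables for the three criteria, and an SVG overlap boxplot
#' when the graphics device supports it.
#'
#' @param x a `StrategyComparison`.
#' @param dir output directory (created if needed).
#' @return the paths written, invisibly.
#' @export
write_comparison <- function(x, dir) {
  stopifnot(inherits(x, "StrategyComparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("report.json", "classification.csv",
                            "robustness.csv", "enrichment_factor.csv"))
  payload <- list(strategies = lapply(x$reports, report_to_list),
                  overlap_rank_sum_p = as.list(x$overlap_tests))
  jsonlite::write_json(payload, paths[1], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(x$classification_table, paths[2], row.names = FALSE)
  utils::write.csv(x$robustness_table, paths[3], row.names = FALSE)
  utils::write.csv(x$ef_table, paths[4], row.names = FALSE)
  if (isTRUE(capabilities("cairo"))) {
    svg_path <- file.path(dir, "overlaps.svg")
    grDevices::svg(svg_path, width = 6, height = 4)
    plot_overlaps(x)
    grDevices::dev.off()
    paths <- c(paths, svg_path)
  }
  invisible(paths)
}

#' Boxplot of the per-strategy overlap distributions
#'
#' @param x a `StrategyComparison`.
#' @return invisibly, the list of overlap vectors plotted.
#' @export
plot_overlaps <- function(x) {
  ov <- lapply(x$reports, function(r) r$robustness$overlaps)
  graphics::boxplot(ov, ylab = "overlap value", ylim = c(0, 1),
                    col = c("palegreen", "darkgreen", "steelblue", "orange"),
                    main = "Marker robustness by strategy")
  invisible(ov)
}
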