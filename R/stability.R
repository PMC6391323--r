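#' Stratified half-sample of a peak table
#'
#' Draws `floor(n_g / 2)` samples per group, without replacement,
#' reproducibly from `seed`.
#'
#' @param x a `PeakTable` with >= 4 samples per group.
#' @param seed RNG seed.
#' @return a `PeakTable` containing the drawn samples.
#' @export
half_sample <- function(x, seed = 1L) {
  validate_peak_table(x)
  set.seed(seed)
  idx <- integer(0)
  for (g in c("case", "control")) {
    gi <- which(x$groups == g)
    if (length(gi) < 4L) {
      stop("group '", g, "' has ", length(gi), " samples; need >= 4 to half-sample")
    }
    idx <- c(idx, sample(gi, floor(length(gi) / 2)))
  }
  subset_samples(x, sort(idx))
}

#' Overlap value between two marker lists
#'
#' The Dice-type robustness statistic `2 * |a intersect b| / (|a| + |b|)`;
#' 1 iff the lists are identical as sets, 0 for disjoint lists. Two empty
#' lists give 0 by convention.
#'
#' @param a,b marker lists (`MarkerList` or character identifier vectors).
#' @return overlap value in `[0, 1]`.
#' @export
overlap <- function(a, b) {
  ia <- unique(marker_ids(a))
  ib <- unique(marker_ids(b))
  if (!length(ia) && !length(ib)) return(0)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

#' Half-sampling robustness report
#'
#' The robustness criterion: `n_iter` stratified half-samples of the
#' pretreated table, a Student's-t marker list (p < `alpha`) from each, all
#' `choose(n_iter, 2)` pairwise overlap values (45 for the canonical 10
#' samplings), their median, the union of all identified markers, and the
#' co-identification profile — counts and percentages (over the union) of
#' markers found in all `n_iter` lists and in at least
#' `n_iter - 1, ..., n_iter - 4` of them.
#'
#' @param x pretreated `PeakTable`.
#' @param n_iter number of half-samplings (default 10).
#' @param alpha t-test significance threshold.
#' @param seed master seed; per-iteration seeds are derived from it.
#' @return an `OverlapReport` list.
#' @export
robustness_report <- function(x, n_iter = 10L, alpha = 0.05, seed = 1L) {
  validate_peak_table(x)
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, n_iter)
  lists <- lapply(iter_seeds, function(s) {
    marker_ids(ttest_markers(half_sample(x, seed = s), alpha = alpha))
  })
  pairs <- utils::combn(n_iter, 2L)
  overlaps <- apply(pairs, 2L, function(ij) overlap(lists[[ij[1]]], lists[[ij[2]]]))
  coident <- coidentification_profile(lists)
  structure(list(
    n_iterations = n_iter,
    marker_counts = lengths(lists),
    marker_lists = lists,
    overlaps = as.numeric(overlaps),
    median_overlap = stats::median(overlaps),
    total_identified = attr(coident, "union_size"),
    coidentification = coident,
    alpha = alpha, seed = seed
  ), class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat("OverlapReport:", x$n_iterations, "half-samplings,",
      length(x$overlaps), "pairwise overlaps\n")
  cat(sprintf("  median overlap %.3f; union of markers %d\n",
              x$median_overlap, x$total_identified))
  for (r in seq_len(nrow(x$coidentification))) {
    cat(sprintf("  %-6s %5d (%.2f%%)\n", x$coidentification$threshold[r],
                x$coidentification$count[r], x$coidentification$percent[r]))
  }
  invisible(x)
}

#' Co-identification profile of resampled marker lists
#'
#' For marker lists from `n` resamplings, counts the markers discovered
#' simultaneously by all `n` lists and by at least `n-1, ..., n-4` of them;
#' percentages are taken over the union of all identified markers.
#'
#' @param lists a list of marker ID vectors (or `MarkerList`s).
#' @return data.frame with `threshold`, `count`, `percent`; the union size
#'   is attached as attribute `union_size`.
#' @export
coidentification_profile <- function(lists) {
  lists <- lapply(lists, function(l) unique(marker_ids(l)))
  n <- length(lists)
  tab <- table(unlist(lists, use.names = FALSE))
  union_size <- length(tab)
  thresholds <- n - 0:4
  thresholds <- thresholds[thresholds >= 1L]
  counts <- vapply(thresholds, function(k) sum(tab >= k), integer(1))
  out <- data.frame(
    threshold = ifelse(thresholds == n, sprintf("N=%d", n),
                       sprintf("N>=%d", thresholds)),
    count = counts,
    percent = if (union_size > 0) 100 * counts / union_size
              else rep(NA_real_, length(counts)),
    stringsAsFactors = FALSE
  )
  attr(out, "union_size") <- union_size
  out
}

#' Compare two overlap distributions
#'
#' One-sided Wilcoxon rank-sum test that `x` is stochastically greater than
#' `y` (normal approximation with tie correction). Fully tied input is
#' degenerate: p = 1 with a `degenerate` attribute.
#'
#' @param x,y numeric overlap vectors.
#' @return p-value (attribute `degenerate` flags all-tied input).
#' @export
compare_overlap_distributions <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1L) {
    return(structure(1, degenerate = TRUE))
  }
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
  )
  structure(p, degenerate = FALSE)
}

#' Enrichment factor of a marker list
#'
#' `EF = (n_true_identified / n_identified) / (n_true_detected / n_detected)`:
#' the true-marker rate among identified metabolites relative to the rate
#' expected from random selection out of the detected (annotated) universe.
#' EF = 1 means no better than random selection.
#'
#' @param n_true_identified true markers among the identified metabolites.
#' @param n_identified identified (annotated) metabolites.
#' @param n_true_detected true markers among the detected universe.
#' @param n_detected size of the detected annotated universe.
#' @return the enrichment factor.
#' @export
enrichment_factor <- function(n_true_identified, n_identified,
                              n_true_detected, n_detected) {
  if (n_identified <= 0 || n_detected <= 0 || n_true_detected <= 0) {
    stop("enrichment factor undefined: zero denominator")
  }
  if (n_true_identified > n_identified || n_true_detected > n_detected) {
    stop("true-marker counts cannot exceed their totals")
  }
  (n_true_identified / n_identified) / (n_true_detected / n_detected)
}

#' Enrichment-factor report for a marker list
#'
#' Assembles the four counts behind the enrichment factor from a marker
#' list, an annotation of the full detected feature universe, and the
#' true-marker set: the detected annotated universe and its true-marker
#' coverage, the identified annotated set and its coverage, and the EF.
#'
#' @param markers a `MarkerList` of identified features.
#' @param annotation an [annotate()] result covering the detected features.
#' @param truth a `TrueMarkerSet` (character metabolite IDs).
#' @return an `EFReport` list: the four counts, `ef` (`NA` with a flag when
#'   the truth set is disjoint from the universe), `low_support` (`TRUE`
#'   when at most one true marker was identified), and the identified /
#'   universe metabolite ID sets (used for results integration).
#' @export
ef_report <- function(markers, annotation, truth) {
  stopifnot(inherits(annotation, "AnnotationResult"))
  truth <- as.character(truth)
  universe <- annotation$universe
  identified <- annotated_metabolites(markers, annotation)
  ef_from_sets(identified, universe, truth)
}

#' Enrichment-factor report from metabolite ID sets
#'
#' Lower-level constructor used both by [ef_report()] and by the
#' results-integration strategy (which intersects per-experiment sets
#' before scoring).
#'
#' @param identified character IDs of identified annotated metabolites.
#' @param universe character IDs of the detected annotated universe.
#' @param truth character true-marker IDs.
#' @return an `EFReport`.
#' @export
ef_from_sets <- function(identified, universe, truth) {
  identified <- unique(as.character(identified))
  universe <- unique(as.character(universe))
  truth <- unique(as.character(truth))
  n_detected <- length(universe)
  n_true_detected <- length(intersect(truth, universe))
  n_identified <- length(identified)
  n_true_identified <- length(intersect(truth, identified))
  ef <- if (n_detected > 0 && n_true_detected > 0 && n_identified > 0) {
    enrichment_factor(n_true_identified, n_identified,
                      n_true_detected, n_detected)
  } else {
    NA_real_
  }
  structure(list(
    n_detected_annotated = n_detected,
    n_true_detected = n_true_detected,
    n_identified_annotated = n_identified,
    n_true_identified = n_true_identified,
    ef = ef,
    ef_undefined = is.na(ef),
    low_support = n_true_identified <= 1L,
    identified_ids = identified,
    universe_ids = universe
  ), class = "EFReport")
}

#' @export
print.EFReport <- function(x, ...) {
  cat("EFReport:", x$n_identified_annotated, "identified /",
      x$n_detected_annotated, "detected metabolites;",
      x$n_true_identified, "/", x$n_true_detected, "true markers\n")
  if (x$ef_undefined) {
    cat("  EF undefined (no true marker in the detected universe or empty set)\n")
  } else {
    cat(sprintf("  EF = %.2f%s\n", x$ef,
                if (x$low_support) "  [low support: <= 1 true marker identified]" else ""))
  }
  invisible(x)
}
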