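#' Per-feature pooled-variance Student's t-test
#'
#' Vectorised two-sample, two-sided Student's t-test (equal-variance pooled
#' form) of case vs control for every feature. Features with zero pooled
#' variance get p = 1 by convention, with a warning.
#'
#' @param x a pretreated `PeakTable` with >= 2 samples per group.
#' @return data.frame with one row per feature: `feature_key`, `mz`, `rt`,
#'   `t`, `p_value`.
#' @export
row_ttest <- function(x) {
  validate_peak_table(x)
  M <- x$intensities
  if (anyNA(M)) stop("missing values present; pretreat the table first")
  g <- x$groups == "case"
  n1 <- sum(g); n2 <- sum(!g)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group for the t-test")
  X1 <- M[, g, drop = FALSE]
  X2 <- M[, !g, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1L)
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  df <- n1 + n2 - 2L
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- sp2 <= 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance feature(s); p set to 1")
    tt[degenerate] <- 0
    p[degenerate] <- 1
  }
  data.frame(feature_key = feature_keys(x), mz = x$mz, rt = x$rt,
             t = tt, p_value = p, stringsAsFactors = FALSE)
}

new_marker_list <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("MarkerList", "data.frame")
  df
}

#' Marker identifiers of a marker list
#' @param m a `MarkerList`, a data.frame with a `feature_key` column, or a
#'   character vector of identifiers.
#' @return character vector.
#' @export
marker_ids <- function(m) {
  if (is.character(m)) return(m)
  if (is.data.frame(m) && "feature_key" %in% names(m)) return(m$feature_key)
  stop("cannot extract marker identifiers from this object")
}

#' Select differential features by Student's t-test
#'
#' Features with two-sided pooled-t p < `alpha`; no multiplicity correction
#' (raw p-value counts are the convention of the benchmarking design).
#'
#' @param x pretreated `PeakTable`.
#' @param alpha significance threshold.
#' @return a `MarkerList` data.frame (`feature_key`, `mz`, `rt`, `p_value`).
#' @export
ttest_markers <- function(x, alpha = 0.05) {
  tt <- row_ttest(x)
  new_marker_list(tt[tt$p_value < alpha,
                     c("feature_key", "mz", "rt", "p_value"), drop = FALSE])
}

#' PLS-DA variable importance in projection (VIP)
#'
#' Fits a PLS1 regression (NIPALS) of the binary group indicator on the
#' autoscaled feature matrix and returns per-feature VIP scores,
#' `VIP_j = sqrt( P * sum_a SSY_a w_ja^2 / sum_a SSY_a )` with normalised
#' component weights `w`, so that `sum_j VIP_j^2 = P` exactly. Constant
#' features are guarded with unit variance during autoscaling (their VIP is
#' then driven by a zero weight).
#'
#' @param x pretreated `PeakTable`.
#' @param n_components number of PLS components (capped at the data rank).
#' @return named numeric vector of VIP scores (names = feature keys).
#' @export
plsda_vip <- function(x, n_components = 2L) {
  validate_peak_table(x)
  M <- x$intensities
  if (anyNA(M)) stop("missing values present; pretreat the table first")
  X <- t(M)                               # samples x features
  P <- ncol(X)
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  const <- sdv <= 0
  if (any(const)) {
    warning(sum(const), " constant feature(s); unit variance substituted")
    sdv[const] <- 1
  }
  X <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  y <- as.numeric(x$groups == "case")
  y <- y - mean(y)
  A <- min(n_components, n - 1L, P)
  if (A < 1L) stop("n_components must be >= 1 and data must have rank >= 1")
  Wmat <- matrix(0, P, A)
  ssy <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(X, y))
    nw <- sqrt(sum(w^2))
    if (nw <= .Machine$double.eps) { A <- a - 1L; break }
    w <- w / nw
    t_sc <- drop(X %*% w)
    tt <- sum(t_sc^2)
    p_load <- drop(crossprod(X, t_sc)) / tt
    q <- sum(y * t_sc) / tt
    X <- X - tcrossprod(t_sc, p_load)
    y <- y - q * t_sc
    Wmat[, a] <- w
    ssy[a] <- q^2 * tt                    # y-variance explained by component a
  }
  if (A < 1L) stop("PLS deflation degenerate: no usable component")
  Wmat <- Wmat[, seq_len(A), drop = FALSE]
  ssy <- ssy[seq_len(A)]
  vip <- sqrt(P * drop(Wmat^2 %*% ssy) / sum(ssy))
  names(vip) <- feature_keys(x)
  vip
}

#' Select markers by PLS-DA VIP and t-test p-value
#'
#' The conventional conjunction rule: VIP > `vip_threshold` AND univariate
#' Student's-t p < `alpha`.
#'
#' @param x pretreated `PeakTable`.
#' @param vip_threshold VIP cutoff (conventionally 1).
#' @param alpha t-test significance threshold.
#' @param n_components PLS components for the VIP model.
#' @return a `MarkerList` data.frame (`feature_key`, `mz`, `rt`, `p_value`,
#'   `vip`).
#' @export
plsda_markers <- function(x, vip_threshold = 1, alpha = 0.05,
                          n_components = 2L) {
  tt <- row_ttest(x)
  tt$vip <- unname(plsda_vip(x, n_components))
  sel <- tt$vip > vip_threshold & tt$p_value < alpha
  new_marker_list(tt[sel, c("feature_key", "mz", "rt", "p_value", "vip"),
                     drop = FALSE])
}

#' Annotate features against a reference library within a ppm window
#'
#' A feature matches a library record iff
#' `|observed_mz - expected_mz| <= tol_ppm * 1e-6 * expected_mz`, where the
#' expected m/z is the neutral mass plus (positive mode) or minus (negative
#' mode) the proton mass. The mapping is one-to-many; the universe is the
#' set of distinct metabolites hit by any feature.
#'
#' @param features a `PeakTable`, or a numeric vector of observed m/z. When
#'   a numeric vector is given, names (or the m/z strings) are used as keys.
#' @param lib a `ReferenceLibrary`.
#' @param tol_ppm annotation tolerance in ppm (default 20).
#' @param mode `"positive"` or `"negative"` ionisation.
#' @return an `AnnotationResult`: `mapping` (named list feature key ->
#'   character vector of metabolite IDs), `universe` (distinct matched IDs),
#'   `universe_size`.
#' @export
annotate <- function(features, lib, tol_ppm = 20,
                     mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(lib, "ReferenceLibrary"))
  if (!nrow(lib)) stop("empty reference library")
  if (inherits(features, "PeakTable")) {
    mz <- features$mz
    keys <- feature_keys(features)
  } else {
    mz <- as.numeric(features)
    keys <- if (!is.null(names(features))) names(features)
            else sprintf("%.*g", 15L, mz)
  }
  adduct <- if (mode == "positive") PROTON_MASS else -PROTON_MASS
  emz <- lib$neutral_mass + adduct
  ord <- order(emz)
  emz_s <- emz[ord]
  ids_s <- lib$metabolite_id[ord]
  halfmax <- tol_ppm * 1e-6 * max(emz_s)
  mapping <- vector("list", length(mz))
  names(mapping) <- keys
  for (i in seq_along(mz)) {
    lo <- findInterval(mz[i] - halfmax, emz_s) + 1L
    hi <- findInterval(mz[i] + halfmax, emz_s)
    if (hi >= lo) {
      cand <- lo:hi
      ok <- abs(mz[i] - emz_s[cand]) <= tol_ppm * 1e-6 * emz_s[cand]
      mapping[[i]] <- ids_s[cand[ok]]
    } else {
      mapping[[i]] <- character(0)
    }
  }
  universe <- unique(unlist(mapping, use.names = FALSE))
  structure(list(mapping = mapping, universe = universe,
                 universe_size = length(universe),
                 tol_ppm = tol_ppm, mode = mode),
            class = "AnnotationResult")
}

#' @export
print.AnnotationResult <- function(x, ...) {
  hits <- lengths(x$mapping)
  cat("AnnotationResult:", length(x$mapping), "features,",
      sum(hits > 0), "annotated,", x$universe_size,
      "distinct metabolites (", x$tol_ppm, "ppm,", x$mode, "mode )\n")
  invisible(x)
}

#' Metabolites annotated from a set of marker features
#'
#' Convenience: union of the library hits of the given marker features,
#' looked up in a precomputed [annotate()] result.
#'
#' @param markers a `MarkerList` (or character feature keys).
#' @param annotation an `AnnotationResult` covering those features.
#' @return character vector of metabolite IDs.
#' @export
annotated_metabolites <- function(markers, annotation) {
  keys <- marker_ids(markers)
  miss <- setdiff(keys, names(annotation$mapping))
  if (length(miss)) stop("marker feature '", miss[1], "' not in annotation result")
  unique(unlist(annotation$mapping[keys], use.names = FALSE))
}
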