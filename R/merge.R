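#' m/z matching tolerance
#'
#' @param value positive tolerance value.
#' @param unit `"Da"` (absolute) or `"ppm"` (relative; evaluated against the
#'   mean m/z of the candidate pair).
#' @return an `MzTolerance` object.
#' @export
mz_tolerance <- function(value, unit = c("Da", "ppm")) {
  unit <- match.arg(unit)
  if (!is.finite(value) || value <= 0) stop("tolerance value must be > 0")
  structure(list(value = value, unit = unit), class = "MzTolerance")
}

tol_limit <- function(tol, mz_a, mz_b) {
  if (tol$unit == "ppm") tol$value * 1e-6 * (mz_a + mz_b) / 2 else tol$value
}

#' Match the features of two experiments by m/z
#'
#' Greedy one-to-one matching: all candidate pairs within the tolerance are
#' ranked by |delta m/z| ascending and accepted when both endpoints are still
#' unused. Retention time is not used. A ppm tolerance is evaluated as
#' |delta| <= value * 1e-6 * mean(mz_a, mz_b).
#'
#' @param a,b `PeakTable`s or numeric m/z vectors.
#' @param tol an [mz_tolerance()]; the shipped default is 0.05 Da.
#' @return a `MatchSet`: `pairs` (data.frame of `a`, `b` feature indices and
#'   `delta_mz`), `unmatched_a`, `unmatched_b`.
#' @export
match_features <- function(a, b, tol = mz_tolerance(0.05, "Da")) {
  mz_a <- if (inherits(a, "PeakTable")) a$mz else as.numeric(a)
  mz_b <- if (inherits(b, "PeakTable")) b$mz else as.numeric(b)
  stopifnot(inherits(tol, "MzTolerance"))
  na <- length(mz_a)
  nb <- length(mz_b)
  empty <- function() structure(
    list(pairs = data.frame(a = integer(), b = integer(), delta_mz = numeric()),
         unmatched_a = seq_len(na), unmatched_b = seq_len(nb), tol = tol),
    class = "MatchSet")
  if (na == 0L || nb == 0L) return(empty())

  ord_b <- order(mz_b)
  sb <- mz_b[ord_b]
  # widest possible window (ppm window grows with m/z; pad by 2x for safety)
  half <- if (tol$unit == "ppm") 2 * tol$value * 1e-6 * max(mz_a, sb) else tol$value
  ca <- integer(0); cb <- integer(0)
  for (i in seq_len(na)) {
    lo <- findInterval(mz_a[i] - half, sb) + 1L
    hi <- findInterval(mz_a[i] + half, sb)
    if (hi >= lo) {
      ca <- c(ca, rep.int(i, hi - lo + 1L))
      cb <- c(cb, ord_b[lo:hi])
    }
  }
  if (!length(ca)) return(empty())
  delta <- mz_a[ca] - mz_b[cb]
  ok <- abs(delta) <= tol_limit(tol, mz_a[ca], mz_b[cb])
  ca <- ca[ok]; cb <- cb[ok]; delta <- delta[ok]
  if (!length(ca)) return(empty())

  o <- order(abs(delta), pmin(mz_a[ca], mz_b[cb]), pmax(mz_a[ca], mz_b[cb]))
  ca <- ca[o]; cb <- cb[o]; delta <- delta[o]
  used_a <- logical(length(mz_a)); used_b <- logical(length(mz_b))
  keep <- logical(length(ca))
  for (p in seq_along(ca)) {
    if (!used_a[ca[p]] && !used_b[cb[p]]) {
      keep[p] <- TRUE
      used_a[ca[p]] <- TRUE
      used_b[cb[p]] <- TRUE
    }
  }
  pairs <- data.frame(a = ca[keep], b = cb[keep], delta_mz = delta[keep])
  pairs <- pairs[order(pairs$a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(seq_len(na), pairs$a),
                 unmatched_b = setdiff(seq_len(nb), pairs$b),
                 tol = tol),
            class = "MatchSet")
}

#' @export
print.MatchSet <- function(x, ...) {
  cat("MatchSet:", nrow(x$pairs), "matched pairs (tol ", x$tol$value,
      x$tol$unit, "); ", length(x$unmatched_a), "/", length(x$unmatched_b),
      "unmatched in a/b\n")
  invisible(x)
}

#' Merge two experiments' peak tables over their matched features
#'
#' Keeps only the matched (common) features; the merged feature m/z is the
#' intensity-weighted mean of the pair (weights = each feature's mean
#' observed intensity; arithmetic mean when weights are unavailable), RT the
#' arithmetic mean. Samples are concatenated with their experiment tags
#' preserved; intensities and missingness are carried over unchanged.
#' Colliding sample IDs are suffixed with the experiment tag.
#'
#' @param a,b the two `PeakTable`s.
#' @param matches a `MatchSet` from [match_features()] on `a`, `b`.
#' @return merged `PeakTable`.
#' @export
merge_tables <- function(a, b, matches = match_features(a, b)) {
  stopifnot(inherits(matches, "MatchSet"))
  pr <- matches$pairs
  if (!nrow(pr)) stop("no common features between the two tables")
  wa <- rowMeans(a$intensities[pr$a, , drop = FALSE], na.rm = TRUE)
  wb <- rowMeans(b$intensities[pr$b, , drop = FALSE], na.rm = TRUE)
  wa[!is.finite(wa)] <- 0
  wb[!is.finite(wb)] <- 0
  wsum <- wa + wb
  # convex-combination form keeps mz/rt bit-exact when the pair coincides
  frac <- ifelse(wsum > 0, wb / wsum, 0.5)
  mz <- a$mz[pr$a] + frac * (b$mz[pr$b] - a$mz[pr$a])
  rt <- a$rt[pr$a] + (b$rt[pr$b] - a$rt[pr$a]) / 2
  ids_a <- a$sample_ids
  ids_b <- b$sample_ids
  clash <- intersect(ids_a, ids_b)
  if (length(clash)) {
    warning(length(clash), " sample ID(s) collide between experiments; ",
            "suffixing with experiment tag")
    ids_a <- ifelse(ids_a %in% clash, paste(ids_a, a$experiment, sep = "_"), ids_a)
    ids_b <- ifelse(ids_b %in% clash, paste(ids_b, b$experiment, sep = "_"), ids_b)
    if (anyDuplicated(c(ids_a, ids_b))) {  # identical experiment tags (self-merge)
      ids_a <- ifelse(a$sample_ids %in% clash, paste0(ids_a, ".1"), ids_a)
      ids_b <- ifelse(b$sample_ids %in% clash, paste0(ids_b, ".2"), ids_b)
    }
  }
  peak_table(mz, rt,
             cbind(a$intensities[pr$a, , drop = FALSE],
                   b$intensities[pr$b, , drop = FALSE]),
             c(ids_a, ids_b), c(a$groups, b$groups),
             c(a$experiment, b$experiment))
}
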