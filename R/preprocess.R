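#' Feature-wise K-nearest-neighbour missing-value imputation
#'
#' Each missing cell (feature f, sample s) is replaced by the mean, over the
#' k features nearest to f, of their values in sample s. Nearness is
#' Euclidean distance between feature intensity profiles computed on the
#' samples where both features are observed, scaled to a per-sample RMS so
#' that neighbours with different overlap sizes are comparable. Neighbours
#' are required to share at least `min_overlap` observed samples with f;
#' when no neighbour meets that requirement the threshold relaxes to 1
#' before falling back to the feature's own observed mean.
#'
#' @param x a `PeakTable`; every feature must have at least one observed
#'   value.
#' @param k number of neighbours, `1 <= k < n_features`.
#' @param min_overlap minimum mutually observed samples for a feature to
#'   count as a neighbour candidate.
#' @return a `PeakTable` with no missing values; observed cells untouched.
#' @export
knn_impute <- function(x, k = 10L, min_overlap = 3L) {
  validate_peak_table(x)
  M <- x$intensities
  nf <- nrow(M)
  if (k < 1L || k >= nf) stop("k must satisfy 1 <= k < n_features (", nf, ")")
  obs <- !is.na(M)
  dead <- which(rowSums(obs) == 0L)
  if (length(dead)) {
    stop("feature ", dead[1], " has no observed values; remove it before imputation")
  }
  need <- which(rowSums(!obs) > 0L)
  if (!length(need)) return(x)

  A <- M
  A[!obs] <- 0
  W <- obs + 0
  A2 <- A^2
  # Sum of squared differences over mutually observed samples, for the rows
  # needing imputation against all rows (zero-filled matrix identity).
  SS <- A2[need, , drop = FALSE] %*% t(W) + W[need, , drop = FALSE] %*% t(A2) -
    2 * (A[need, , drop = FALSE] %*% t(A))
  OV <- W[need, , drop = FALSE] %*% t(W)
  D <- sqrt(pmax(SS, 0) / OV)  # RMS distance; NaN where no overlap
  D[OV == 0] <- Inf

  fell_back <- 0L
  for (ii in seq_along(need)) {
    f <- need[ii]
    d <- D[ii, ]
    d[f] <- Inf
    eligible <- which(is.finite(d) & OV[ii, ] >= min_overlap)
    if (!length(eligible)) eligible <- which(is.finite(d))  # relax threshold
    nn <- eligible[order(d[eligible])][seq_len(min(k, length(eligible)))]
    fmean <- mean(M[f, obs[f, ]])
    for (s in which(!obs[f, ])) {
      vals <- M[nn, s]
      vals <- vals[!is.na(vals)]
      if (length(vals)) {
        M[f, s] <- mean(vals)
      } else {
        M[f, s] <- fmean
        fell_back <- fell_back + 1L
      }
    }
  }
  if (fell_back > 0L) {
    warning(fell_back, " cell(s) had no neighbour observed in the target sample; ",
            "feature mean used")
  }
  out <- x
  out$intensities <- M
  out
}

#' MSTUS normalization
#'
#' Divides each sample by its "MS total useful signal": the summed intensity
#' of the features shared by all samples (i.e. observed in every sample
#' before imputation). After normalization the shared-feature total of every
#' sample equals 1, making the table invariant to per-sample dilution.
#'
#' @param x a `PeakTable` with no missing values (impute first).
#' @param shared_features integer index of the features defining the total
#'   useful signal; defaults to all features (correct for a table that had
#'   no missingness). [pretreat()] passes the pre-imputation shared set.
#' @return normalized `PeakTable`.
#' @export
mstus_normalize <- function(x, shared_features = NULL) {
  validate_peak_table(x)
  M <- x$intensities
  if (anyNA(M)) stop("missing values present; run knn_impute() before MSTUS")
  if (is.null(shared_features)) shared_features <- seq_len(nrow(M))
  if (!length(shared_features)) stop("empty shared-feature set")
  totals <- colSums(M[shared_features, , drop = FALSE])
  bad <- which(totals <= 0)
  if (length(bad)) {
    stop("sample '", x$sample_ids[bad[1]], "' has non-positive shared-feature total")
  }
  out <- x
  out$intensities <- sweep(M, 2L, totals, "/")
  out
}

#' Pretreat a peak table: KNN imputation then MSTUS normalization
#'
#' The stated pipeline order is imputation first, normalization second; the
#' MSTUS denominator uses the features that were observed in all samples
#' *before* imputation. If no feature is complete, the total signal over all
#' features is used instead, with a warning.
#'
#' @param x a `PeakTable`.
#' @param k KNN neighbour count.
#' @param min_overlap see [knn_impute()].
#' @return pretreated `PeakTable`.
#' @export
pretreat <- function(x, k = 10L, min_overlap = 3L) {
  obs <- !is.na(x$intensities)
  shared <- which(rowSums(!obs) == 0L)
  imputed <- knn_impute(x, k = k, min_overlap = min_overlap)
  if (!length(shared)) {
    warning("no feature observed in all samples; falling back to total-signal normalization")
    shared <- seq_len(n_features(x))
  }
  mstus_normalize(imputed, shared)
}
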