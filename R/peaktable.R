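#' Construct a peak table
#'
#' A `PeakTable` is the package's central container: a features x samples
#' intensity matrix from an aligned LC-MS run, with per-feature m/z (Da) and
#' retention time (seconds), per-sample group labels (`"case"` / `"control"`)
#' and a per-sample experiment (batch) tag. Missing intensities are `NA`.
#'
#' @param mz numeric vector of feature m/z values (Da), all > 0.
#' @param rt numeric vector of feature retention times (seconds).
#' @param intensities numeric matrix, features x samples; `NA` marks a
#'   missing (undetected) intensity; observed values must be non-negative.
#' @param sample_ids character vector of unique sample identifiers.
#' @param groups per-sample label, each `"case"` or `"control"`.
#' @param experiment per-sample experiment/batch tag (recycled if length 1).
#' @return An object of class `PeakTable`.
#' @export
peak_table <- function(mz, rt, intensities, sample_ids, groups,
                       experiment = "exp1") {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  dimnames(intensities) <- NULL
  if (length(experiment) == 1L) {
    experiment <- rep(experiment, length(sample_ids))
  }
  x <- structure(
    list(
      mz = as.numeric(mz),
      rt = as.numeric(rt),
      intensities = intensities,
      sample_ids = as.character(sample_ids),
      groups = as.character(groups),
      experiment = as.character(experiment)
    ),
    class = "PeakTable"
  )
  validate_peak_table(x)
}

#' Validate a peak table
#'
#' Checks the `PeakTable` invariants: matching dimensions, positive m/z,
#' known group labels, at least one case and one control, unique sample IDs,
#' non-negative observed intensities.
#'
#' @param x a `PeakTable`.
#' @return `x`, invisibly unchanged, or a hard error naming the offender.
#' @export
validate_peak_table <- function(x) {
  stopifnot(inherits(x, "PeakTable"))
  nf <- length(x$mz)
  ns <- length(x$sample_ids)
  if (length(x$rt) != nf) {
    stop("rt length (", length(x$rt), ") != number of features (", nf, ")")
  }
  if (!all(dim(x$intensities) == c(nf, ns))) {
    stop("intensity matrix is ", nrow(x$intensities), " x ",
         ncol(x$intensities), " but expected ", nf, " x ", ns)
  }
  if (length(x$groups) != ns || length(x$experiment) != ns) {
    stop("groups/experiment length does not match number of samples (", ns, ")")
  }
  if (nf > 0 && any(!is.finite(x$mz) | x$mz <= 0)) {
    stop("non-positive m/z at feature ", which(!is.finite(x$mz) | x$mz <= 0)[1])
  }
  bad <- !(x$groups %in% c("case", "control"))
  if (any(bad)) {
    stop("unknown group label '", x$groups[bad][1], "' for sample '",
         x$sample_ids[bad][1], "' (expected 'case' or 'control')")
  }
  if (!any(x$groups == "case") || !any(x$groups == "control")) {
    stop("peak table must contain at least one case and one control sample")
  }
  dup <- duplicated(x$sample_ids)
  if (any(dup)) {
    stop("duplicate sample ID '", x$sample_ids[dup][1], "'")
  }
  obs <- x$intensities[!is.na(x$intensities)]
  if (length(obs) && any(obs < 0)) {
    stop("negative intensity values are not allowed")
  }
  invisible(x)
}

#' @export
print.PeakTable <- function(x, ...) {
  cat("PeakTable:", n_features(x), "features x", n_samples(x), "samples\n")
  cat("  groups:     ", sum(x$groups == "case"), "case /",
      sum(x$groups == "control"), "control\n")
  cat("  experiments:", paste(unique(x$experiment), collapse = ", "), "\n")
  pmiss <- mean(is.na(x$intensities)) * 100
  cat(sprintf("  missing:     %.1f%%\n", pmiss))
  invisible(x)
}

#' Number of features in a peak table
#' @param x a `PeakTable`.
#' @return integer count.
#' @export
n_features <- function(x) length(x$mz)

#' Number of samples in a peak table
#' @param x a `PeakTable`.
#' @return integer count.
#' @export
n_samples <- function(x) length(x$sample_ids)

#' Feature keys of a peak table
#'
#' Marker identity within one dataset is the feature key, a string built
#' from the (m/z, RT) pair at full precision.
#'
#' @param x a `PeakTable`.
#' @return character vector, one key per feature.
#' @export
feature_keys <- function(x) {
  sprintf("%.*g@%.*g", 15L, x$mz, 15L, x$rt)
}

#' Subset the samples of a peak table
#' @param x a `PeakTable`.
#' @param idx integer or logical sample index.
#' @return a `PeakTable` with the selected samples.
#' @export
subset_samples <- function(x, idx) {
  peak_table(x$mz, x$rt, x$intensities[, idx, drop = FALSE],
             x$sample_ids[idx], x$groups[idx], x$experiment[idx])
}

#' Subset the features of a peak table
#' @param x a `PeakTable`.
#' @param idx integer or logical feature index.
#' @return a `PeakTable` with the selected features.
#' @export
subset_features <- function(x, idx) {
  peak_table(x$mz[idx], x$rt[idx], x$intensities[idx, , drop = FALSE],
             x$sample_ids, x$groups, x$experiment)
}

#' Concatenate the samples of two peak tables over identical features
#'
#' Internal helper used when reassembling classification splits; both tables
#' must have the same features in the same order.
#' @noRd
combine_samples <- function(a, b) {
  stopifnot(identical(a$mz, b$mz), identical(a$rt, b$rt))
  peak_table(a$mz, a$rt, cbind(a$intensities, b$intensities),
             c(a$sample_ids, b$sample_ids), c(a$groups, b$groups),
             c(a$experiment, b$experiment))
}

#' Read a peak table from CSV/TSV
#'
#' The table file has a header `mz,rt,<sample1>,...` with features as rows;
#' empty cells and the token `NA` are read as missing. The metadata file maps
#' `sample_id` to `group` and `experiment`. Field separator is taken from the
#' file extension (`.tsv`/`.txt` = tab, otherwise comma).
#'
#' @param path peak table file.
#' @param metadata_path sample metadata file with columns
#'   `sample_id,group,experiment`.
#' @return a validated `PeakTable`.
#' @export
read_peak_table <- function(path, metadata_path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!all(c("mz", "rt") %in% names(df))) {
    stop("peak table '", path, "' must have 'mz' and 'rt' columns")
  }
  sample_cols <- setdiff(names(df), c("mz", "rt"))
  if (!length(sample_cols)) stop("peak table '", path, "' has no sample columns")

  msep <- if (grepl("\\.(tsv|txt)$", metadata_path, ignore.case = TRUE)) "\t" else ","
  meta <- utils::read.table(metadata_path, header = TRUE, sep = msep,
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "experiment")
  if (!all(need %in% names(meta))) {
    stop("metadata '", metadata_path, "' must have columns ",
         paste(need, collapse = ", "))
  }
  missing_meta <- setdiff(sample_cols, meta$sample_id)
  if (length(missing_meta)) {
    stop("sample '", missing_meta[1], "' in peak table has no metadata entry")
  }
  meta <- meta[match(sample_cols, meta$sample_id), ]
  peak_table(df$mz, df$rt,
             as.matrix(df[, sample_cols, drop = FALSE]),
             sample_cols, meta$group, meta$experiment)
}

#' Write a peak table to CSV/TSV
#'
#' Inverse of [read_peak_table()]: writes the intensity table (missing cells
#' as empty fields, m/z at full double precision) and the sample metadata.
#'
#' @param x a `PeakTable`.
#' @param path output table file (`.tsv`/`.txt` = tab-separated).
#' @param metadata_path output metadata file.
#' @return `x`, invisibly.
#' @export
write_peak_table <- function(x, path, metadata_path) {
  validate_peak_table(x)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  mat <- x$intensities
  df <- data.frame(mz = sprintf("%.*g", 17L, x$mz),
                   rt = sprintf("%.*g", 17L, x$rt),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(x$sample_ids)) {
    col <- ifelse(is.na(mat[, j]), "", sprintf("%.*g", 17L, mat[, j]))
    df[[x$sample_ids[j]]] <- col
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = x$sample_ids, group = x$groups,
                     experiment = x$experiment, stringsAsFactors = FALSE)
  msep <- if (grepl("\\.(tsv|txt)$", metadata_path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(meta, metadata_path, sep = msep, quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read a reference metabolite library
#'
#' A TSV with columns `metabolite_id`, `name`, `neutral_mass` (monoisotopic,
#' Da), standing in for an HMDB-like compound database.
#'
#' @param path library file.
#' @return a `data.frame` of class `ReferenceLibrary`.
#' @export
read_reference_library <- function(path) {
  lib <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = c(metabolite_id = "character"))
  reference_library(lib)
}

#' Construct/validate a reference library
#' @param records data.frame with columns `metabolite_id`, `name`,
#'   `neutral_mass`.
#' @return the validated `ReferenceLibrary`.
#' @export
reference_library <- function(records) {
  need <- c("metabolite_id", "name", "neutral_mass")
  if (!all(need %in% names(records))) {
    stop("reference library needs columns ", paste(need, collapse = ", "))
  }
  records$metabolite_id <- as.character(records$metabolite_id)
  dup <- duplicated(records$metabolite_id)
  if (any(dup)) stop("duplicate metabolite_id '", records$metabolite_id[dup][1], "'")
  if (any(!is.finite(records$neutral_mass) | records$neutral_mass <= 0)) {
    stop("neutral_mass must be positive and finite")
  }
  class(records) <- c("ReferenceLibrary", "data.frame")
  records
}

#' Write a reference library to TSV
#' @param lib a `ReferenceLibrary`.
#' @param path output file.
#' @return `lib`, invisibly.
#' @export
write_reference_library <- function(lib, path) {
  utils::write.table(as.data.frame(lib)[, c("metabolite_id", "name", "neutral_mass")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(lib)
}

#' Load the true-marker set
#'
#' With no argument, returns the packaged set of twelve experimentally
#' validated serum metabolite markers that differentiate hepatocellular
#' carcinoma from cirrhosis patients (HMDB accession suffixes). The packaged
#' fixture also lists creatinine, a urine-only marker, which is excluded
#' because the benchmark design is serum-based.
#'
#' A custom file may either be a tab-separated table with `metabolite_id`
#' and `biofluid` columns (urine-only rows are dropped) or a plain list of
#' IDs, one per line.
#'
#' @param path optional file; `NULL` uses the packaged fixture.
#' @return character vector of metabolite IDs (class `TrueMarkerSet`).
#' @export
load_true_markers <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hcc_cir_true_markers.tsv",
                        package = "metastrat", mustWork = TRUE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("true-marker file '", path, "' is empty")
  ids <- if (grepl("\t", lines[1]) && grepl("metabolite_id", lines[1])) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            colClasses = "character")
    if ("biofluid" %in% names(df)) {
      df <- df[grepl("serum", df$biofluid, ignore.case = TRUE), ]
    }
    df$metabolite_id
  } else {
    trimws(lines)
  }
  ids <- unique(ids[nzchar(ids)])
  if (!length(ids)) stop("true-marker file '", path, "' contains no IDs")
  structure(ids, class = "TrueMarkerSet")
}
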