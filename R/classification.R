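#' Stratified train/test/independent split
#'
#' Random partition of the samples, stratified by group. Within each group
#' the split sizes are `floor(frac * n)` with the remainder distributed to
#' the splits with the largest fractional parts (earlier splits win ties).
#'
#' @param x a `PeakTable`.
#' @param fractions length-3 non-negative vector summing to 1
#'   (train, test, independent).
#' @param seed RNG seed for the partition.
#' @return list with `train`, `test`, `independent`; empty splits are
#'   `NULL`. Each non-`NULL` split keeps at least one sample per group or an
#'   error is raised.
#' @export
split_dataset <- function(x, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  validate_peak_table(x)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be 3 non-negative numbers summing to 1")
  }
  set.seed(seed)
  assign <- integer(n_samples(x))
  for (g in c("case", "control")) {
    idx <- which(x$groups == g)
    n <- length(idx)
    base <- floor(fractions * n)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(fractions * n - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    if (any(fractions > 0 & base == 0L)) {
      stop("cannot stratify: group '", g, "' (n=", n,
           ") leaves an empty non-zero split")
    }
    assign[sample(idx)] <- rep(1:3, base)
  }
  out <- lapply(1:3, function(s) {
    i <- which(assign == s)
    if (!length(i)) NULL else subset_samples(x, i)
  })
  names(out) <- c("train", "test", "independent")
  out
}

#' Confusion-matrix classification metrics
#'
#' SEN = TP/(TP+FN); SPE = TN/(TN+FP); ACC = (TP+TN)/total;
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)).
#' Metrics with a zero denominator are `NA` and flagged in `$undefined`.
#'
#' @param tp,tn,fp,fn non-negative confusion counts (case = positive).
#' @return list of class `ClassificationMetrics` with `sen`, `spe`, `acc`,
#'   `mcc`, the counts, and `undefined` (character vector of undefined
#'   metric names).
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion matrix")
  undef <- character(0)
  sen <- if (tp + fn > 0) tp / (tp + fn) else { undef <- c(undef, "sen"); NA_real_ }
  spe <- if (tn + fp > 0) tn / (tn + fp) else { undef <- c(undef, "spe"); NA_real_ }
  acc <- (tp + tn) / total
  denom <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else {
    undef <- c(undef, "mcc"); NA_real_
  }
  structure(list(sen = sen, spe = spe, acc = acc, mcc = mcc,
                 counts = c(tp = tp, tn = tn, fp = fp, fn = fn),
                 undefined = undef),
            class = "ClassificationMetrics")
}

#' Area under the ROC curve (rank formulation)
#'
#' Mann-Whitney AUC: the probability that a random case scores above a
#' random control, with ties contributing 1/2 (midranks).
#'
#' @param scores per-sample decision values (higher = more case-like).
#' @param labels per-sample labels; `"case"`/`"control"`, logical, or 0/1
#'   with 1/`TRUE` = case.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "case"
  } else {
    as.logical(labels)
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---------------------------------------------------------------------------
# Internal soft-margin C-SVC with RBF kernel, trained by simplified SMO.
# Deterministic: the second working-set index is chosen by max |E_i - E_j|.
# Adequate for the benchmark-sized problems this package targets (n <~ 500).

rbf_kernel <- function(X, Z, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  exp(-gamma * pmax(d2, 0))
}

svm_rbf_fit <- function(X, y, cost = 1, gamma = 1 / ncol(X),
                        tol = 1e-3, max_quiet_passes = 5L, max_iter = 5000L) {
  stopifnot(all(y %in% c(-1, 1)))
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  alpha <- numeric(n)
  b <- 0
  quiet <- 0L
  iter <- 0L
  while (quiet < max_quiet_passes && iter < max_iter) {
    changed <- 0L
    E <- drop(K %*% (alpha * y)) + b - y
    for (i in seq_len(n)) {
      Ei <- drop(crossprod(K[, i], alpha * y)) + b - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < cost) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        E[i] <- Ei
        gap <- abs(Ei - E)
        gap[i] <- -Inf
        j <- which.max(gap)
        if (j == i) next
        Ej <- drop(crossprod(K[, j], alpha * y)) + b - y[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old)
          H <- min(cost, cost + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - cost)
          H <- min(cost, ai_old + aj_old)
        }
        if (H - L < 1e-12) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < cost) b1
             else if (aj > 0 && aj < cost) b2
             else (b1 + b2) / 2
        E <- drop(K %*% (alpha * y)) + b - y
        changed <- changed + 1L
      }
    }
    iter <- iter + 1L
    quiet <- if (changed == 0L) quiet + 1L else 0L
  }
  sv <- alpha > 1e-8
  list(X = X[sv, , drop = FALSE], coef = (alpha * y)[sv], b = b,
       gamma = gamma, cost = cost)
}

svm_rbf_decision <- function(model, X) {
  if (!nrow(model$X)) return(rep(model$b, nrow(X)))
  drop(rbf_kernel(X, model$X, model$gamma) %*% model$coef) + model$b
}

#' Classification-capacity evaluation of a pretreated dataset
#'
#' The classification criterion: features are selected by pooled Student's
#' t-test (p < `alpha`) on the train+test samples, an RBF-kernel SVM is
#' tuned on the test split over a small fixed cost/gamma lattice, the final
#' model is refit on train+test, and SEN/SPE/ACC/MCC plus rank-based AUC are
#' computed on the held-out independent split only. The independent split
#' never influences feature selection or fitting.
#'
#' @param train,test,independent `PeakTable` splits with identical features
#'   (`test` may be `NULL`, in which case default hyperparameters are used).
#' @param alpha feature-selection significance threshold.
#' @param cost_grid,gamma_scale_grid hyperparameter lattice; gamma values
#'   are `gamma_scale_grid / n_selected_features`.
#' @return `ClassificationMetrics` with `auc`, `n_features_selected`, and
#'   the chosen hyperparameters attached.
#' @export
fit_and_evaluate <- function(train, test, independent, alpha = 0.05,
                             cost_grid = c(0.1, 1, 10),
                             gamma_scale_grid = c(0.1, 1, 10)) {
  if (is.null(train) || is.null(independent)) {
    stop("train and independent splits are required")
  }
  devel <- if (is.null(test)) train else combine_samples(train, test)
  tt <- row_ttest(devel)
  sel <- which(tt$p_value < alpha)
  if (!length(sel)) {
    warning("no feature passed t-test selection; using all features")
    sel <- seq_len(n_features(devel))
  }

  prep <- function(tab) t(log1p(tab$intensities[sel, , drop = FALSE]))
  Xd <- prep(devel)
  mu <- colMeans(Xd)
  sdv <- apply(Xd, 2L, stats::sd)
  sdv[sdv <= 0] <- 1
  std <- function(X) sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  Xd <- std(Xd)
  yd <- ifelse(devel$groups == "case", 1, -1)

  P <- length(sel)
  best <- list(cost = 1, gamma = 1 / P)
  if (!is.null(test) && n_samples(test) >= 2L &&
      length(unique(test$groups)) == 2L) {
    Xtr <- std(prep(train))
    ytr <- ifelse(train$groups == "case", 1, -1)
    Xte <- std(prep(test))
    yte <- ifelse(test$groups == "case", 1, -1)
    best_acc <- -Inf
    for (cost in cost_grid) {
      for (gs in gamma_scale_grid) {
        m <- svm_rbf_fit(Xtr, ytr, cost = cost, gamma = gs / P)
        acc <- mean(sign(svm_rbf_decision(m, Xte)) == yte)
        if (acc > best_acc + 1e-12) {
          best_acc <- acc
          best <- list(cost = cost, gamma = gs / P)
        }
      }
    }
  }
  model <- svm_rbf_fit(Xd, yd, cost = best$cost, gamma = best$gamma)

  Xi <- std(prep(independent))
  dec <- svm_rbf_decision(model, Xi)
  truth <- independent$groups == "case"
  pred <- dec > 0
  cm <- confusion_metrics(tp = sum(pred & truth), tn = sum(!pred & !truth),
                          fp = sum(pred & !truth), fn = sum(!pred & truth))
  cm$auc <- roc_auc(dec, independent$groups)
  cm$n_features_selected <- P
  cm$hyperparameters <- best
  cm
}

#' @export
print.ClassificationMetrics <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.3f", v))
  cat("ClassificationMetrics: SEN", fmt(x$sen), "SPE", fmt(x$spe),
      "ACC", fmt(x$acc), "MCC", fmt(x$mcc))
  if (!is.null(x$auc)) cat(" AUC", fmt(x$auc))
  cat("\n")
  invisible(x)
}
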