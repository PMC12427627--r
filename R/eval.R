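# Classification metrics, ROC analysis, stratified cross-validation and
# permutation importance. The positive class is ASD (label 1) throughout.

#' Confusion matrix counts
#'
#' @param y_true,y_pred 0/1 vectors of equal length (1 = ASD = positive).
#' @return A `confusion_matrix` list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  structure(list(
    TP = sum(y_true == 1L & y_pred == 1L),
    TN = sum(y_true == 0L & y_pred == 0L),
    FP = sum(y_true == 0L & y_pred == 1L),
    FN = sum(y_true == 1L & y_pred == 0L)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2L, byrow = TRUE,
              dimnames = list(c("Actual: ASD", "Actual: Control"),
                              c("Predicted: ASD", "Predicted: Control")))
  print(m)
  invisible(x)
}

#' Derived metrics from a confusion matrix
#'
#' Closed-form accuracy, precision, recall (sensitivity), specificity and
#' F1. Ratios with a zero denominator are reported as `NaN` with a warning,
#' never silently zeroed.
#'
#' @param cm A `confusion_matrix`.
#' @param auc Optional AUC to carry into the report.
#' @return A `metrics_report` list with the metrics, `n_correct` and the
#'   confusion matrix.
#' @export
metrics_from_confusion <- function(cm, auc = NA_real_) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tot <- cm$TP + cm$TN + cm$FP + cm$FN
  if (tot == 0L) stop("empty confusion matrix")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " is undefined (zero denominator)", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  precision <- safe_div(cm$TP, cm$TP + cm$FP, "precision")
  recall <- safe_div(cm$TP, cm$TP + cm$FN, "recall")
  f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0) {
    warning("F1 is undefined", call. = FALSE); NaN
  } else 2 * precision * recall / (precision + recall)
  structure(list(
    accuracy = (cm$TP + cm$TN) / tot,
    precision = precision,
    recall = recall,
    specificity = safe_div(cm$TN, cm$TN + cm$FP, "specificity"),
    f1 = f1,
    auc = auc,
    n_correct = cm$TP + cm$TN,
    confusion = cm
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  for (m in c("accuracy", "precision", "recall", "specificity", "f1", "auc")) {
    cat(sprintf("  %-12s %s\n", m, format(x[[m]], digits = 4)))
  }
  cat(sprintf("  %-12s %d\n", "n_correct", x$n_correct))
  invisible(x)
}

#' ROC curve and AUC
#'
#' The AUC is computed with the rank (Mann-Whitney) formulation using
#' midranks for ties; the curve is a threshold sweep over the unique scores.
#' The two agree: trapezoidal integration of the returned curve reproduces
#' the rank AUC to numerical precision.
#'
#' @param y_true 0/1 labels (both classes required).
#' @param scores Numeric scores, larger = more ASD-like.
#' @return List with `curve` (data.frame `threshold`, `fpr`, `tpr`,
#'   endpoints (0,0) and (1,1)) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(scores), all(y_true %in% 0:1))
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)                                   # midranks for ties
  auc <- (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & y_true == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & y_true == 0L), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fp / n0),
                      tpr = c(0, tp / n1))
  list(curve = curve, auc = auc)
}

#' Stratified k-fold partition
#'
#' Folds are disjoint, cover every subject, and preserve class proportions
#' to within one subject per fold.
#'
#' @param y 0/1 labels (each class count >= k).
#' @param k Number of folds.
#' @param seed Integer seed for the within-class shuffle.
#' @return List of `k` integer index vectors.
#' @export
stratified_kfold <- function(y, k, seed = 1L) {
  y <- as.integer(y)
  k <- as.integer(k)
  for (cls in unique(y)) {
    if (sum(y == cls) < k) stop("class ", cls, " has fewer than k subjects")
  }
  with_seed(seed, {
    folds <- vector("list", k)
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      assign_to <- rep(seq_len(k), length.out = length(idx))
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
    lapply(folds, sort)
  })
}

#' Permutation importance of input dimensions
#'
#' Importance of a dimension is the mean drop in accuracy when that
#' dimension is permuted across subjects, over `n_repeats` seeded
#' permutations.
#'
#' @param predict_fun Function taking a matrix and returning 0/1 labels.
#' @param X Input matrix (subjects x dims).
#' @param y True 0/1 labels.
#' @param n_repeats Permutations per dimension.
#' @param seed Integer seed.
#' @return data.frame with `dimension`, `importance`, sorted decreasing
#'   (ties broken by dimension name).
#' @export
permutation_importance <- function(predict_fun, X, y, n_repeats = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  base_acc <- mean(predict_fun(X) == y)
  dims <- colnames(X) %||% sprintf("dim_%03d", seq_len(ncol(X)))
  imp <- with_seed(seed, {
    vapply(seq_len(ncol(X)), function(j) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[, j] <- Xp[sample.int(nrow(X)), j]
        base_acc - mean(predict_fun(Xp) == y)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  ord <- order(-imp, dims)
  data.frame(dimension = dims[ord], importance = imp[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
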