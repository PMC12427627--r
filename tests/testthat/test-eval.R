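test_that("confusion counts follow the definitions", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(cm[c("TP", "TN", "FP", "FN")]),
               c(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  cm2 <- confusion(c(1, 0), c(0, 1))
  expect_equal(unlist(cm2[c("TP", "TN", "FP", "FN")]),
               c(TP = 0L, TN = 0L, FP = 1L, FN = 1L))
  expect_error(confusion(c(1, 0), c(1)), "length")
})

test_that("metrics match closed forms and flag undefined ratios", {
  set.seed(20)
  for (r in 1:20) {
    n <- sample(5:60, 1)
    yt <- sample(0:1, n, replace = TRUE)
    yp <- sample(0:1, n, replace = TRUE)
    cm <- confusion(yt, yp)
    expect_equal(cm$TP + cm$TN + cm$FP + cm$FN, n)
    rep_ <- suppressWarnings(metrics_from_confusion(cm))
    expect_equal(rep_$accuracy, mean(yt == yp))
    expect_equal(rep_$n_correct, sum(yt == yp))
    if (sum(yp == 1) > 0)
      expect_equal(rep_$precision, sum(yt == 1 & yp == 1) / sum(yp == 1))
    if (sum(yt == 1) > 0)
      expect_equal(rep_$recall, sum(yt == 1 & yp == 1) / sum(yt == 1))
  }
  ws <- capture_warnings(out <- metrics_from_confusion(confusion(c(0, 0), c(0, 0))))
  expect_match(ws, "undefined", all = TRUE)
  expect_true(any(grepl("precision", ws)))
  expect_true(is.nan(out$precision))
  expect_equal(out$accuracy, 1)
})

test_that("rank AUC agrees with pair counting, trapezoids and pROC", {
  y <- c(0, 0, 1, 1); s <- c(0.1, 0.4, 0.35, 0.8)
  expect_equal(roc_auc(y, s)$auc, 0.75)            # 3 of 4 class pairs concordant
  expect_equal(roc_auc(c(0, 1, 0, 1), c(0, 1, 0, 1))$auc, 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.3, 4))$auc, 0.5)
  set.seed(21)
  for (r in 1:10) {
    n <- sample(10:80, 1)
    yt <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    out <- roc_auc(yt, sc)
    expect_equal(out$auc, oracle_auc(yt, sc), tolerance = 1e-12)
    # trapezoidal integral of the sweep curve reproduces the rank AUC
    trap <- sum(diff(out$curve$fpr) *
                  (out$curve$tpr[-1] + out$curve$tpr[-nrow(out$curve)]) / 2)
    expect_lt(abs(out$auc - trap), 1e-9)
    expect_equal(out$auc, as.numeric(suppressMessages(
      pROC::auc(pROC::roc(yt, sc, quiet = TRUE, direction = "<")))))
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("roc curve is monotone with (0,0) and (1,1) endpoints", {
  set.seed(22)
  out <- roc_auc(sample(0:1, 50, replace = TRUE, prob = c(.4, .6)), runif(50))
  expect_equal(out$curve$fpr[1], 0)
  expect_equal(out$curve$tpr[1], 0)
  expect_equal(out$curve$fpr[nrow(out$curve)], 1)
  expect_equal(out$curve$tpr[nrow(out$curve)], 1)
  expect_true(all(diff(out$curve$fpr) >= 0))
  expect_true(all(diff(out$curve$tpr) >= 0))
})

test_that("stratified folds partition subjects and balance classes", {
  y <- rep(c(0, 1), each = 5)
  folds <- stratified_kfold(y, 5, seed = 1)
  expect_length(folds, 5)
  expect_true(all(sapply(folds, function(f) sum(y[f] == 0) == 1 && sum(y[f] == 1) == 1)))
  expect_equal(sort(unlist(folds)), 1:10)
  expect_identical(folds, stratified_kfold(y, 5, seed = 1))
  set.seed(23)
  y2 <- sample(0:1, 83, replace = TRUE, prob = c(0.3, 0.7))
  folds2 <- stratified_kfold(y2, 4, seed = 2)
  expect_equal(sort(unlist(folds2)), seq_along(y2))
  expect_equal(sum(duplicated(unlist(folds2))), 0)
  props <- sapply(folds2, function(f) mean(y2[f]))
  expect_true(all(abs(props - mean(y2)) < 4 / min(lengths(folds2))))
  expect_error(stratified_kfold(c(0, 1, 1, 1), 2), "fewer")
})

test_that("permutation importance isolates used dimensions", {
  set.seed(24)
  n <- 500
  d <- rnorm(n); a <- rnorm(n)
  y <- as.integer(a + d > 0)
  # unique-copy model: signal d enters through one column
  X1 <- cbind(a = a, b = rnorm(n), d = d)
  f1 <- function(M) as.integer(M[, "a"] + M[, "d"] > 0)
  imp1 <- permutation_importance(f1, X1, y, n_repeats = 10, seed = 3)
  expect_equal(imp1$importance[imp1$dimension == "b"], 0)  # unused dimension
  i_unique <- imp1$importance[imp1$dimension == "d"]
  expect_gt(i_unique, 0)
  # duplicated-copy model: the same signal split over two identical columns
  X2 <- cbind(a = a, dup1 = d, dup2 = d)
  f2 <- function(M) as.integer(M[, "a"] + (M[, "dup1"] + M[, "dup2"]) / 2 > 0)
  imp2 <- permutation_importance(f2, X2, y, n_repeats = 10, seed = 3)
  expect_lt(imp2$importance[imp2$dimension == "dup1"], i_unique)
  expect_lt(imp2$importance[imp2$dimension == "dup2"], i_unique)
  # determinism under a fixed seed
  expect_identical(imp2, permutation_importance(f2, X2, y, n_repeats = 10, seed = 3))
})
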