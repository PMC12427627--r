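test_that("prediction decomposes exactly into effects plus bias", {
  fit <- fitted_gami()
  p <- gami_predict(fit$model, fit$X)
  eff <- gami_effects(fit$model, fit$X)
  recon <- 1 / (1 + exp(-(rowSums(eff) + fit$model$bias)))
  expect_lt(max(abs(unname(p) - recon)), 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  # also on fresh inputs the model has never seen
  set.seed(8)
  Xnew <- matrix(runif(40 * ncol(fit$X)), 40,
                 dimnames = list(NULL, colnames(fit$X)))
  p2 <- gami_predict(fit$model, Xnew)
  e2 <- gami_effects(fit$model, Xnew)
  expect_lt(max(abs(unname(p2) - 1 / (1 + exp(-(rowSums(e2) + fit$model$bias))))),
            1e-6)
})

test_that("pruned effects contribute exactly zero and masks drive the output", {
  fit <- fitted_gami()
  m <- fit$model
  m$main_mask[] <- FALSE
  m$inter_mask[] <- FALSE
  m$bias <- 0
  expect_equal(ncol(gami_effects(m, fit$X)), 0)
  expect_true(all(gami_predict(m, fit$X) == 0.5))   # sigmoid(0)
  m$bias <- 10
  expect_true(all(gami_predict(m, fit$X) > 0.999))  # sigmoid saturation
})

test_that("training reduces the binary cross-entropy on learnable signal", {
  fit <- fitted_gami()
  h <- fit$model$history$main
  expect_lt(h[length(h)], h[1])
})

test_that("feature-count mismatches and degenerate labels are rejected", {
  fit <- fitted_gami()
  expect_error(gami_predict(fit$model, fit$X[, 1:3]), "features")
  expect_error(fit_gami(fit$X, rep(1L, nrow(fit$X))), "both classes")
  expect_error(fit_gami(fit$X * 5, fit$y), "\\[0, 1\\]")
})

test_that("importance scores are normalized, ranked, and recover injected features", {
  fit <- fitted_gami()
  imp <- gami_importance(fit$model, fit$X)
  expect_equal(sum(imp$score), 1, tolerance = 1e-9)
  expect_true(all(diff(imp$score) <= 1e-12))
  # recovery across seeds: most of the top features must be the injected ones
  hits <- sapply(1:5, function(s) {
    co <- generate_cohort(n = 300, n_features = 12, behavioral_effect = 2,
                          n_informative_features = 3, seed = 200 + s)
    X <- apply_preprocessor(fit_preprocessor(co$behavioral), co$behavioral)
    g <- fit_gami(X, unname(co$labels), gami_config(max_interactions = 3L, seed = s))
    top <- gami_top_features(g, X, n = 3)
    truth <- sprintf("FEAT_%02d", co$truth$informative_features)
    sum(top %in% truth)
  })
  expect_gte(sum(hits >= 2), 4)
})

test_that("a single informative feature ranks first", {
  ok <- 0
  for (s in 1:3) {
    co <- generate_cohort(n = 300, n_features = 8, behavioral_effect = 2,
                          n_informative_features = 1, seed = 300 + s)
    X <- apply_preprocessor(fit_preprocessor(co$behavioral), co$behavioral)
    g <- fit_gami(X, unname(co$labels), gami_config(seed = s))
    top <- gami_top_features(g, X, n = 1)
    if (top == sprintf("FEAT_%02d", co$truth$informative_features)) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("interaction screening finds a planted multiplicative pair", {
  ok <- 0
  for (s in 1:5) {
    set.seed(s)
    n <- 400; p <- 5
    X <- matrix(runif(n * p), n, p, dimnames = list(NULL, sprintf("x%d", 1:p)))
    eta <- 10 * (X[, 1] - 0.5) * (X[, 2] - 0.5)
    y <- as.integer(runif(n) < 1 / (1 + exp(-eta)))
    main <- fit_gami(X, y, gami_config(max_interactions = 0L, seed = s))
    L <- select_interactions(X, y, main, k = 1)
    if (nrow(L) == 1 && L[1, 1] == 1 && L[1, 2] == 2) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("interaction screening respects k and candidate bounds", {
  fit <- fitted_gami()
  expect_equal(nrow(select_interactions(fit$X, fit$y, fit$model, k = 0)), 0)
  X2 <- fit$X[, 1:2]
  m2 <- fit_gami(X2, fit$y, gami_config(max_interactions = 0L, epochs = 2L, seed = 1))
  L <- select_interactions(X2, fit$y, m2, k = 5)
  expect_lte(nrow(L), 1)                           # only one candidate pair exists
})

test_that("partial dependence matches the additive component", {
  fit <- fitted_gami()
  feat <- which(fit$model$main_mask)[1]
  pd <- gami_partial_dependence(fit$model, feat, grid = seq(0, 1, length.out = 50))
  expect_equal(nrow(pd), 50)
  # curve values agree with the effect column when X hits the grid points
  name <- fit$model$feature_names[feat]
  Xg <- fit$X[1:50, , drop = FALSE]
  Xg[, feat] <- pd$grid
  eff <- gami_effects(fit$model, Xg)
  expect_lt(max(abs(eff[, name] - pd$effect)), 1e-6)
  # pruned feature errors by name
  m <- fit$model
  m$main_mask[feat] <- FALSE
  expect_error(gami_partial_dependence(m, feat), name)
})

test_that("label-permuted data gives chance-level cross-validated AUC", {
  co <- generate_cohort(n = 250, n_features = 12, behavioral_effect = 2,
                        n_informative_features = 3, seed = 17)
  X <- apply_preprocessor(fit_preprocessor(co$behavioral), co$behavioral)
  y <- with_seed <- unname(co$labels)
  set.seed(99)
  yp <- sample(y)                                   # break the X-y link
  folds <- stratified_kfold(yp, 5, seed = 3)
  scores <- numeric(length(yp))
  for (f in folds) {
    g <- fit_gami(X[-f, ], yp[-f], gami_config(max_interactions = 3L, seed = 4))
    scores[f] <- gami_predict(g, X[f, ])
  }
  auc <- roc_auc(yp, scores)$auc
  expect_gte(auc, 0.4)
  expect_lte(auc, 0.6)
})
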