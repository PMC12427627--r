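trained_hypernet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(10)
      n <- 200
      Z <- rbind(matrix(rnorm(n / 2 * 32), ncol = 32),
                 matrix(rnorm(n / 2 * 32, mean = 4 / sqrt(32)), ncol = 32))
      y <- rep(0:1, each = n / 2)
      cache <<- list(model = train_hypernet(Z, y, seed = 11), Z = Z, y = y)
    }
    cache
  }
})

test_that("generated parameters have the printed shapes (562 scalars)", {
  th <- generate_params(trained_hypernet()$model, rnorm(32))
  expect_equal(dim(th$W1), c(16L, 32L))
  expect_length(th$b1, 16L)
  expect_equal(dim(th$W2), c(2L, 16L))
  expect_length(th$b2, 2L)
  expect_equal(length(th$W1) + length(th$b1) + length(th$W2) + length(th$b2), 562L)
  expect_true(all(sapply(th, function(p) all(is.finite(p)))))
  expect_error(generate_params(trained_hypernet()$model, rnorm(5)), "length")
})

test_that("a zeroed hypernetwork generates all-zero classifiers", {
  m <- trained_hypernet()$model
  m$params$Wo[] <- 0; m$params$bo[] <- 0
  th <- generate_params(m, rnorm(32))
  expect_true(all(th$W1 == 0) && all(th$b1 == 0) &&
                all(th$W2 == 0) && all(th$b2 == 0))
})

test_that("distinct latents generate distinct parameters", {
  m <- trained_hypernet()$model
  set.seed(12)
  t1 <- generate_params(m, rnorm(32))
  t2 <- generate_params(m, rnorm(32))
  expect_gt(max(abs(t1$W1 - t2$W1)), 0)
})

test_that("personalized forward matches the dense-algebra oracle", {
  set.seed(13)
  for (r in 1:10) {
    z <- rnorm(32)
    th <- list(W1 = matrix(rnorm(16 * 32, sd = 0.3), 16, 32), b1 = rnorm(16),
               W2 = matrix(rnorm(2 * 16, sd = 0.3), 2, 16), b2 = rnorm(2))
    p <- personalized_forward(z, th)
    expect_lt(max(abs(p - oracle_personalized_forward(z, th))), 1e-6)
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
  # zero parameters -> equal logits -> [0.5, 0.5]
  z0 <- list(W1 = matrix(0, 16, 32), b1 = rep(0, 16),
             W2 = matrix(0, 2, 16), b2 = rep(0, 2))
  expect_equal(unname(personalized_forward(rnorm(32), z0)), c(0.5, 0.5))
  # bias saturation
  zb <- z0; zb$b2 <- c(0, 10)
  expect_gt(personalized_forward(rnorm(32), zb)["p_asd"], 0.9999)
  zn <- z0; zn$b2 <- c(NA, 0)
  expect_error(personalized_forward(rnorm(32), zn), "finite")
})

test_that("training separates shifted clusters and is seed-deterministic", {
  hn <- trained_hypernet()
  pred <- hypernet_predict(hn$model, hn$Z)
  expect_gte(mean(pred$labels == hn$y), 0.99)
  expect_lt(hn$model$history[length(hn$model$history)], hn$model$history[1])
  m2 <- train_hypernet(hn$Z, hn$y, seed = 11)
  expect_identical(hypernet_predict(m2, hn$Z), pred)
  expect_error(train_hypernet(hn$Z, rep(0L, nrow(hn$Z))), "both classes")
})

test_that("probability rows normalize and argmax drives labels (tie -> Control)", {
  hn <- trained_hypernet()
  pred <- hypernet_predict(hn$model, hn$Z)
  expect_true(all(abs(rowSums(pred$probs) - 1) < 1e-6))
  expect_equal(pred$labels, as.integer(pred$probs[, "p_asd"] > pred$probs[, "p_control"]))
  # exact tie via zeroed generator => probabilities 0.5/0.5 => Control
  m0 <- hn$model
  m0$params$Wo[] <- 0; m0$params$bo[] <- 0
  p0 <- hypernet_predict(m0, hn$Z[1:5, ])
  expect_true(all(p0$probs == 0.5))
  expect_true(all(p0$labels == 0L))
})

test_that("permuted labels give chance-level held-out predictions", {
  # The generated-parameter model is expressive enough to memorize random
  # labels in-sample, so the honest null check is on held-out subjects:
  # accuracy inside the 95% binomial band around 0.5 across repetitions.
  accs <- sapply(1:4, function(r) {
    set.seed(140 + r)
    Z <- matrix(rnorm(160 * 16), ncol = 16)
    y <- sample(rep(0:1, 80))
    m <- train_hypernet(Z[1:100, ], y[1:100], seed = 15 + r)
    mean(hypernet_predict(m, Z[101:160, ])$labels == y[101:160])
  })
  band <- 1.96 * sqrt(0.25 / 60)
  expect_gte(mean(accs), 0.5 - band)
  expect_lte(mean(accs), 0.5 + band)
})

test_that("personalization: generated weights vary across subjects, fixed MLP has one set", {
  hn <- trained_hypernet()
  th1 <- generate_params(hn$model, hn$Z[1, ])
  th2 <- generate_params(hn$model, hn$Z[150, ])
  expect_gt(sd(c(th1$W1 - th2$W1)), 0)
  fm <- fit_fixed_mlp(hn$Z, hn$y, seed = 16)
  expect_length(fm$params$W1, 32 * 16)             # one shared parameter set
  pr <- predict(fm, hn$Z)
  expect_true(all(abs(rowSums(pr$probs) - 1) < 1e-6))
  # with the same short full-batch schedule the shared-weight MLP learns the
  # separable structure only partially - well above chance, below the
  # personalized classifier
  expect_gte(mean(pr$labels == hn$y), 0.7)
  expect_lte(mean(pr$labels == hn$y), mean(hypernet_predict(hn$model, hn$Z)$labels == hn$y))
})
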