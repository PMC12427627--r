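test_that("anatomical adjacency marks face-sharing regions only", {
  # two abutting blocks
  a <- array(0L, c(4, 4, 4)); a[1:2, , ] <- 1L; a[3:4, , ] <- 2L
  expect_equal(unname(atlas_adjacency(a)), matrix(c(0, 1, 1, 0), 2))
  # separated by background
  b <- array(0L, c(5, 4, 4)); b[1:2, , ] <- 1L; b[4:5, , ] <- 2L
  expect_equal(unname(atlas_adjacency(b)), matrix(0L, 2, 2))
  # octant atlas: every corner block touches exactly 3 others
  oct <- generate_toy_atlas(c(4, 4, 4), 8)
  A <- atlas_adjacency(oct)
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) == 0))
  expect_true(all(rowSums(A) == 3))
  expect_error(atlas_adjacency(array(1L, c(3, 3, 3))), "at least 2")
})

test_that("normalized propagation operator matches hand-computed values", {
  # connected pair: A+I = ones(2), degrees 2 => all entries 1/2
  Ahat <- normalized_adjacency(matrix(c(0, 1, 1, 0), 2))
  expect_equal(Ahat, matrix(0.5, 2, 2))
  # isolated node keeps only its self-loop
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  Ah <- normalized_adjacency(A)
  expect_equal(Ah[3, ], c(0, 0, 1))
  expect_true(isSymmetric(Ah))
  expect_true(all(is.finite(Ah)))
})

test_that("roi_pool equals the brute-force voxel loop", {
  set.seed(4)
  atlas <- generate_toy_atlas(c(4, 6, 4), 4)
  fv <- array(rnorm(prod(c(4, 6, 4, 3))), c(4, 6, 4, 3))
  expect_lt(max(abs(roi_pool(fv, atlas) - oracle_roi_pool(fv, atlas))), 1e-6)
  # constant volume pools to the constant
  expect_true(all(roi_pool(array(2.5, c(4, 6, 4)), atlas) == 2.5))
  # indicator volume isolates its region
  ind <- array(0, c(4, 6, 4)); ind[atlas == 1] <- 1
  np <- roi_pool(ind, atlas)
  expect_equal(unname(np[, 1]), c(1, 0, 0, 0))
  expect_error(roi_pool(ind, atlas, labels = c(1, 9)), "9")
})

test_that("patch extraction and its adjoint are exact", {
  set.seed(11)
  d <- c(5L, 4L, 6L)
  x <- matrix(rnorm(prod(d) * 2), ncol = 2)
  g <- matrix(rnorm(prod(d) * 27 * 2), prod(d), 27 * 2)
  lhs <- sum(asdfuse:::im2col3(x, d) * g)
  rhs <- sum(x * asdfuse:::col2im3(g, d))
  expect_lt(abs(lhs - rhs), 1e-9)
  # stacked two-subject call equals two single-subject calls
  x2 <- rbind(x, x)
  expect_equal(asdfuse:::im2col3(x2, d, 2L),
               rbind(asdfuse:::im2col3(x, d), asdfuse:::im2col3(x, d)))
})

test_that("convolution blocks preserve shape, channels and determinism", {
  co <- small_cohort(seed = 2, n = 20)
  cfg <- encoder_config(embed_dim = 16, epochs = 2, seed = 7)
  enc <- fit_mri_encoder(co$volumes, co$atlas, unname(co$labels), cfg)
  f <- cnn_features(co$volumes[[1]], enc)
  expect_equal(dim(f), c(dim(co$atlas), 16L))      # last conv_channels entry
  expect_identical(f, cnn_features(co$volumes[[1]], enc))
  # zero volume with zero biases propagates to zero features
  z <- cnn_features(array(0, dim(co$atlas)), enc)
  expect_true(all(abs(z) <= max(abs(enc$params$bc1)) * sum(abs(enc$params$Wc2)) +
                    max(abs(enc$params$bc2)) + 1e-12))
  expect_error(cnn_features(array(0, c(3, 3, 3)), enc), "shape")
})

test_that("embeddings have fixed length and are seed-reproducible", {
  co <- small_cohort(seed = 3, n = 16)
  cfg <- encoder_config(embed_dim = 24, epochs = 2, seed = 5)
  e1 <- fit_mri_encoder(co$volumes, co$atlas, unname(co$labels), cfg)
  e2 <- fit_mri_encoder(co$volumes, co$atlas, unname(co$labels), cfg)
  m1 <- mri_embed(e1, co$volumes)
  m2 <- mri_embed(e2, co$volumes)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(16L, 24L))
  expect_true(all(is.finite(m1)))
  # graph readout contract: embedding length independent of node count
  g <- list(node_features = matrix(rnorm(e1$n_regions * 16), e1$n_regions),
            adjacency = e1$adjacency)
  expect_length(gnn_embed(g, e1), 24L)
  expect_error(fit_mri_encoder(co$volumes, co$atlas, rep(1L, 16), cfg),
               "both classes")
})

test_that("training reduces loss and embeddings separate a planted ROI signal", {
  co <- generate_cohort(n = 120, n_features = 4, roi_effect = 2,
                        informative_rois = 2, shape = c(8, 8, 8), n_rois = 8,
                        seed = 21)
  y <- unname(co$labels)
  enc <- fit_mri_encoder(co$volumes[1:90], co$atlas, y[1:90],
                         encoder_config(embed_dim = 32, seed = 9))
  expect_lt(enc$history[length(enc$history)], enc$history[1])
  emb <- mri_embed(enc, co$volumes)
  # linear probe fitted on train, evaluated on held-out subjects
  probe <- MASS::lda(emb[1:90, ], grouping = y[1:90])
  pred <- as.integer(predict(probe, emb[91:120, ])$class) - 1L
  expect_gte(mean(pred == y[91:120]), 0.8)
})

test_that("null volumes give chance-level probe accuracy", {
  co <- generate_cohort(n = 100, n_features = 4, roi_effect = 0,
                        informative_rois = 2, shape = c(6, 6, 6), n_rois = 8,
                        seed = 22)
  y <- unname(co$labels)
  enc <- fit_mri_encoder(co$volumes[1:70], co$atlas, y[1:70],
                         encoder_config(embed_dim = 16, seed = 10))
  emb <- mri_embed(enc, co$volumes)
  probe <- MASS::lda(emb[1:70, ], grouping = y[1:70])
  pred <- as.integer(predict(probe, emb[71:100, ])$class) - 1L
  acc <- mean(pred == y[71:100])
  band <- 1.96 * sqrt(0.25 / 30)
  expect_gte(acc, 0.5 - band)
  expect_lte(acc, 0.5 + band)
})
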