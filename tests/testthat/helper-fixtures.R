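# Small in-code fixtures shared across test files.

# A compact dual-modality cohort with signal in both branches.
small_cohort <- function(seed = 1L, n = 60L, behavioral_effect = 2,
                         roi_effect = 2, shape = c(6L, 6L, 6L)) {
  generate_cohort(n = n, n_features = 8L,
                  behavioral_effect = behavioral_effect,
                  n_informative_features = 3L,
                  roi_effect = roi_effect, informative_rois = 2L,
                  shape = shape, n_rois = 8L,
                  missing_rate = 0.05, seed = seed)
}

# A fitted behavioral model on a small signal cohort (cached per session).
fitted_gami <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- small_cohort(seed = 5L, n = 120L)
      pre <- fit_preprocessor(co$behavioral)
      X <- apply_preprocessor(pre, co$behavioral)
      cache <<- list(model = fit_gami(X, unname(co$labels),
                                      gami_config(max_interactions = 3L, seed = 2L)),
                     X = X, y = unname(co$labels))
    }
    cache
  }
})

# Hand-rolled dense forward pass for the personalized classifier, kept
# independent of the package implementation.
oracle_personalized_forward <- function(z, theta) {
  h <- as.vector(theta$W1 %*% z) + theta$b1
  h <- ifelse(h > 0, h, 0)
  logits <- as.vector(theta$W2 %*% h) + theta$b2
  exp(logits) / sum(exp(logits))
}

# Brute-force voxel-loop ROI mean pooling.
oracle_roi_pool <- function(features, atlas) {
  fd <- dim(features)
  C <- if (length(fd) == 4L) fd[4L] else 1L
  if (length(fd) == 3L) features <- array(features, c(fd, 1L))
  labels <- sort(unique(as.integer(atlas[atlas > 0])))
  out <- matrix(0, length(labels), C)
  for (r in seq_along(labels)) for (ch in seq_len(C)) {
    acc <- 0; cnt <- 0
    for (i in seq_len(dim(atlas)[1])) for (j in seq_len(dim(atlas)[2]))
      for (k in seq_len(dim(atlas)[3])) {
        if (atlas[i, j, k] == labels[r]) {
          acc <- acc + features[i, j, k, ch]; cnt <- cnt + 1
        }
      }
    out[r, ch] <- acc / cnt
  }
  out
}

# Brute-force per-pair counting AUC (concordant pairs + half ties).
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
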