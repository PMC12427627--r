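# Autoencoder fusion of the behavioral scalar and the MRI embedding.
# Encoder input -> 64 -> 32 (ReLU), decoder 32 -> 64 -> input (ReLU hidden,
# linear output), trained on mean squared reconstruction error. Inputs are
# standardized with training-set z-scores before encoding so the wide MRI
# block cannot drown the one-dimensional behavioral scalar.

#' Concatenate behavioral and MRI embeddings into fusion inputs
#'
#' @param behavioral Per-subject ASD probability from [gami_predict()], or a
#'   matrix of behavioral columns (e.g. probability plus effect
#'   contributions) when a richer behavioral block is wanted.
#' @param mri Matrix (subjects x embed_dim) from [mri_embed()].
#' @return Matrix (subjects x (behavioral cols + embed_dim)); behavioral
#'   columns first.
#' @export
concat_embeddings <- function(behavioral, mri) {
  if (is.null(dim(behavioral))) behavioral <- matrix(behavioral, ncol = 1L,
                                                     dimnames = list(names(behavioral), "asd_prob"))
  mri <- as.matrix(mri)
  if (ncol(mri) < 1L) stop("MRI embedding is empty")
  if (nrow(behavioral) != nrow(mri))
    stop("behavioral and MRI embeddings have different subject counts")
  if (!is.null(rownames(behavioral)) && !is.null(rownames(mri)) &&
      !identical(rownames(behavioral), rownames(mri)))
    stop("behavioral and MRI embeddings are not index-aligned")
  out <- cbind(behavioral, mri)
  colnames(out) <- c(colnames(behavioral) %||% "asd_prob",
                     colnames(mri) %||% sprintf("mri_%03d", seq_len(ncol(mri))))
  out
}

#' Fit the fusion autoencoder
#'
#' @param X Fusion input matrix (subjects x dims), finite.
#' @param bottleneck Latent width (default 32).
#' @param hidden Intermediate width (default 64).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param standardize Standardize columns with training z-scores first.
#' @param seed Integer seed.
#' @return An `autoencoder_model` with encoder/decoder weights, the scaling
#'   constants, `input_dim`, and per-epoch training MSE in `history`.
#' @export
fit_autoencoder <- function(X, bottleneck = 32L, hidden = 64L,
                            epochs = 30L, batch_size = 64L,
                            learning_rate = 1e-3, standardize = TRUE,
                            seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("at least 2 subjects are required")
  if (!all(is.finite(X))) stop("fusion inputs must be finite")
  d <- ncol(X)
  center <- if (standardize) colMeans(X) else rep(0, d)
  scale_ <- if (standardize) apply(X, 2L, sd) else rep(1, d)
  scale_[!is.finite(scale_) | scale_ < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale_, "/")

  with_seed(seed, {
    params <- list(
      We1 = he_init(d, hidden), be1 = rep(0, hidden),
      We2 = he_init(hidden, bottleneck), be2 = rep(0, bottleneck),
      Wd1 = he_init(bottleneck, hidden), bd1 = rep(0, hidden),
      Wd2 = he_init(hidden, d), bd2 = rep(0, d)
    )
    opt <- adam_init(params)
    n <- nrow(Xs)
    history <- numeric(epochs)
    for (epoch in seq_len(epochs)) {
      batches <- minibatches(n, batch_size)
      epoch_loss <- 0
      for (idx in batches) {
        xb <- Xs[idx, , drop = FALSE]
        B <- length(idx)
        z1 <- sweep(xb %*% params$We1, 2L, params$be1, "+"); a1 <- relu(z1)
        z2 <- sweep(a1 %*% params$We2, 2L, params$be2, "+"); z <- relu(z2)
        z3 <- sweep(z %*% params$Wd1, 2L, params$bd1, "+"); a3 <- relu(z3)
        xr <- sweep(a3 %*% params$Wd2, 2L, params$bd2, "+")
        err <- xr - xb
        loss <- mean(err^2)
        epoch_loss <- epoch_loss + loss * B
        dxr <- 2 * err / (B * d)
        grads <- list(Wd2 = t(a3) %*% dxr, bd2 = colSums(dxr))
        da3 <- dxr %*% t(params$Wd2); da3[z3 <= 0] <- 0
        grads$Wd1 <- t(z) %*% da3; grads$bd1 <- colSums(da3)
        dz <- da3 %*% t(params$Wd1); dz[z2 <= 0] <- 0
        grads$We2 <- t(a1) %*% dz; grads$be2 <- colSums(dz)
        da1 <- dz %*% t(params$We2); da1[z1 <= 0] <- 0
        grads$We1 <- t(xb) %*% da1; grads$be1 <- colSums(da1)
        upd <- adam_step(params, grads, opt, lr = learning_rate)
        params <- upd$params; opt <- upd$state
      }
      history[epoch] <- epoch_loss / n
    }
    structure(list(params = params, input_dim = d,
                   bottleneck = as.integer(bottleneck),
                   hidden = as.integer(hidden),
                   center = center, scale = scale_,
                   history = history),
              class = "autoencoder_model")
  })
}

.ae_standardize <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim)
    stop("input has ", ncol(X), " dims; autoencoder expects ", model$input_dim)
  sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
}

#' Encode fusion inputs into the latent code
#'
#' @param model An `autoencoder_model`.
#' @param X Fusion inputs (subjects x input_dim), or a single vector.
#' @return Matrix (subjects x bottleneck) of fused latent codes.
#' @export
ae_encode <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  Xs <- .ae_standardize(model, X)
  a1 <- relu(sweep(Xs %*% model$params$We1, 2L, model$params$be1, "+"))
  z <- relu(sweep(a1 %*% model$params$We2, 2L, model$params$be2, "+"))
  rownames(z) <- rownames(X)
  z
}

#' Decode latent codes back to (standardized) input space
#'
#' @param model An `autoencoder_model`.
#' @param Z Latent matrix (subjects x bottleneck).
#' @return Reconstruction on the original input scale.
#' @export
ae_decode <- function(model, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  a3 <- relu(sweep(Z %*% model$params$Wd1, 2L, model$params$bd1, "+"))
  xr <- sweep(a3 %*% model$params$Wd2, 2L, model$params$bd2, "+")
  sweep(sweep(xr, 2L, model$scale, "*"), 2L, model$center, "+")
}

#' Mean squared reconstruction error
#'
#' Mean over subjects and dimensions of the squared difference between the
#' standardized input and its reconstruction (the training objective).
#'
#' @param model An `autoencoder_model`.
#' @param X Fusion inputs.
#' @return Non-negative scalar.
#' @export
reconstruction_error <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  Xs <- .ae_standardize(model, X)
  Xr <- .ae_standardize(model, ae_decode(model, ae_encode(model, X)))
  mean((Xs - Xr)^2)
}

#' @export
print.autoencoder_model <- function(x, ...) {
  cat("Fusion autoencoder:", x$input_dim, "->", x$hidden, "->", x$bottleneck,
      "->", x$hidden, "->", x$input_dim, "\n")
  cat("  final training MSE:", format(tail_value(x$history), digits = 4), "\n")
  invisible(x)
}
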