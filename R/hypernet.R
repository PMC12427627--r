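# Hypernetwork-generated personalized classifier. A shared network H maps a
# subject's fused latent z to the full weight set theta = (W1, b1, W2, b2) of
# a small MLP, which then classifies that same subject:
# softmax(W2 . ReLU(W1 . z + b1) + b2). Personalization comes only from z;
# H itself is shared and trained end-to-end with cross-entropy.

#' Train the hypernetwork classifier
#'
#' @param Z Latent matrix (subjects x latent dim; 32 for the default fused
#'   code).
#' @param y 0/1 labels (both classes required).
#' @param hidden Hidden width of the hypernetwork itself.
#' @param target_hidden Hidden width of the generated per-subject MLP.
#' @param epochs Training epochs (full-batch, one Adam step per epoch).
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed.
#' @return A `hypernet_model` with the shared weights, dimensions and
#'   per-epoch cross-entropy in `history`.
#' @export
train_hypernet <- function(Z, y, hidden = 64L, target_hidden = 16L,
                           epochs = 30L, learning_rate = 1e-3, seed = 1L) {
  Z <- as.matrix(Z)
  y <- as.integer(y)
  n <- nrow(Z)
  stopifnot(length(y) == n)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  d <- ncol(Z)
  th <- as.integer(target_hidden)
  n_theta <- th * d + th + 2L * th + 2L
  Y <- label_onehot(y)

  with_seed(seed, {
    params <- list(
      Wh = he_init(d, hidden), bh = rep(0, hidden),
      # small head init => initial theta ~ 0 => initial predictions ~ [0.5, 0.5]
      Wo = matrix(rnorm(hidden * n_theta, sd = 1e-2), hidden, n_theta),
      bo = rep(0, n_theta)
    )
    opt <- adam_init(params)
    history <- numeric(epochs)
    for (epoch in seq_len(epochs)) {
      fwd <- .hyper_forward(params, Z, d, th)
      p <- fwd$probs
      history[epoch] <- -mean(log(pmax(p[cbind(seq_len(n), y + 1L)], 1e-12)))
      dlogits <- (p - Y) / n                      # n x 2
      g <- .hyper_backward(params, fwd, Z, dlogits, d, th)
      upd <- adam_step(params, g, opt, lr = learning_rate)
      params <- upd$params; opt <- upd$state
    }
    structure(list(params = params, latent_dim = d, hidden = as.integer(hidden),
                   target_hidden = th, n_theta = n_theta, history = history),
              class = "hypernet_model")
  })
}

# theta layout inside the generated vector (length n_theta):
# [vec(W1) (th*d, W1 is th x d, column-major by z-dim), b1 (th),
#  vec(W2) (2*th, W2 is 2 x th, column-major by hidden), b2 (2)]
.theta_slices <- function(d, th) {
  i1 <- seq_len(th * d)
  i2 <- th * d + seq_len(th)
  i3 <- th * d + th + seq_len(2L * th)
  i4 <- th * d + th + 2L * th + seq_len(2L)
  list(W1 = i1, b1 = i2, W2 = i3, b2 = i4)
}

# Vectorized forward for all subjects: generates Theta (n x n_theta) and runs
# each subject's personalized MLP on its own z.
.hyper_forward <- function(params, Z, d, th) {
  n <- nrow(Z)
  Hz <- sweep(Z %*% params$Wh, 2L, params$bh, "+")
  Ha <- relu(Hz)
  Theta <- sweep(Ha %*% params$Wo, 2L, params$bo, "+")   # n x n_theta
  sl <- .theta_slices(d, th)
  # pre1[s, j] = sum_k W1[s][j, k] * z[s, k] + b1[s][j]
  pre1 <- matrix(0, n, th)
  for (j in seq_len(th)) {
    cols <- sl$W1[j + th * (seq_len(d) - 1L)]            # row j of W1, all k
    pre1[, j] <- rowSums(Theta[, cols, drop = FALSE] * Z)
  }
  pre1 <- pre1 + Theta[, sl$b1, drop = FALSE]
  a1 <- relu(pre1)
  logits <- matrix(0, n, 2L)
  for (cls in 1:2) {
    cols <- sl$W2[cls + 2L * (seq_len(th) - 1L)]         # row cls of W2
    logits[, cls] <- rowSums(Theta[, cols, drop = FALSE] * a1)
  }
  logits <- logits + Theta[, sl$b2, drop = FALSE]
  list(Hz = Hz, Ha = Ha, Theta = Theta, pre1 = pre1, a1 = a1,
       logits = logits, probs = softmax_rows(logits))
}

.hyper_backward <- function(params, fwd, Z, dlogits, d, th) {
  n <- nrow(Z)
  sl <- .theta_slices(d, th)
  Theta <- fwd$Theta
  dTheta <- matrix(0, n, ncol(Theta))
  dTheta[, sl$b2] <- dlogits
  da1 <- matrix(0, n, th)
  for (cls in 1:2) {
    cols <- sl$W2[cls + 2L * (seq_len(th) - 1L)]
    dTheta[, cols] <- dlogits[, cls] * fwd$a1
    da1 <- da1 + dlogits[, cls] * Theta[, cols, drop = FALSE]
  }
  dpre1 <- da1 * (fwd$pre1 > 0)
  dTheta[, sl$b1] <- dpre1
  for (j in seq_len(th)) {
    cols <- sl$W1[j + th * (seq_len(d) - 1L)]
    dTheta[, cols] <- dpre1[, j] * Z
  }
  dHa <- dTheta %*% t(params$Wo)
  dHz <- dHa * (fwd$Hz > 0)
  list(Wh = t(Z) %*% dHz, bh = colSums(dHz),
       Wo = t(fwd$Ha) %*% dTheta, bo = colSums(dTheta))
}

#' Generate the personalized classifier weights for one subject
#'
#' @param model A `hypernet_model`.
#' @param z Latent vector of the fitted length (32 by default).
#' @return A `generated_params` list with `W1` (target_hidden x latent dim),
#'   `b1`, `W2` (2 x target_hidden), `b2`; 562 scalars in total for the
#'   default 16/32 geometry.
#' @export
generate_params <- function(model, z) {
  z <- as.numeric(z)
  if (length(z) != model$latent_dim)
    stop("z has length ", length(z), "; model expects ", model$latent_dim)
  th <- model$target_hidden; d <- model$latent_dim
  Ha <- relu(drop(crossprod(model$params$Wh, z)) + model$params$bh)
  theta <- drop(crossprod(model$params$Wo, Ha)) + model$params$bo
  sl <- .theta_slices(d, th)
  structure(list(
    W1 = matrix(theta[sl$W1], th, d),
    b1 = theta[sl$b1],
    W2 = matrix(theta[sl$W2], 2L, th),
    b2 = theta[sl$b2]
  ), class = "generated_params")
}

#' Run a personalized classifier forward pass
#'
#' `softmax(W2 . ReLU(W1 . z + b1) + b2)` for one subject.
#'
#' @param z Latent vector.
#' @param theta A `generated_params` list (from [generate_params()] or built
#'   by hand).
#' @return Length-2 probability vector `(p_control, p_asd)` summing to 1.
#' @export
personalized_forward <- function(z, theta) {
  if (!all(vapply(theta[c("W1", "b1", "W2", "b2")],
                  function(p) all(is.finite(p)), logical(1L))))
    stop("generated parameters must be finite")
  a1 <- relu(drop(theta$W1 %*% z) + theta$b1)
  logits <- drop(theta$W2 %*% a1) + theta$b2
  e <- exp(logits - max(logits))
  p <- e / sum(e)
  names(p) <- c("p_control", "p_asd")
  p
}

#' Predict classes from latent codes
#'
#' @param model A `hypernet_model`.
#' @param Z Latent matrix (subjects x latent dim).
#' @return List with `labels` (0/1; exact probability ties resolve to 0 =
#'   Control) and `probs` (subjects x 2, columns `p_control`, `p_asd`).
#' @export
hypernet_predict <- function(model, Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) != model$latent_dim)
    stop("Z has ", ncol(Z), " dims; model expects ", model$latent_dim)
  fwd <- .hyper_forward(model$params, Z, model$latent_dim, model$target_hidden)
  probs <- fwd$probs
  colnames(probs) <- c("p_control", "p_asd")
  rownames(probs) <- rownames(Z)
  labels <- as.integer(probs[, 2L] > probs[, 1L])   # tie -> Control (0)
  list(labels = labels, probs = probs)
}

#' @export
predict.hypernet_model <- function(object, newdata, ...) {
  hypernet_predict(object, newdata)
}

#' Train a fixed-weight MLP classifier (the no-hypernetwork variant)
#'
#' A single shared `W1/b1/W2/b2` parameter set with the same geometry as the
#' generated classifiers, trained with full-batch cross-entropy.
#'
#' @inheritParams train_hypernet
#' @return A `fixed_mlp_model`.
#' @export
fit_fixed_mlp <- function(Z, y, hidden = 16L, epochs = 30L,
                          learning_rate = 1e-3, seed = 1L) {
  Z <- as.matrix(Z)
  y <- as.integer(y)
  n <- nrow(Z)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  d <- ncol(Z)
  Y <- label_onehot(y)
  with_seed(seed, {
    # output layer starts near zero so initial logits are ~0 and the few
    # full-batch steps steer the argmax rather than fight the random init
    params <- list(W1 = he_init(d, hidden), b1 = rep(0, hidden),
                   W2 = matrix(rnorm(hidden * 2L, sd = 1e-2), hidden, 2L),
                   b2 = rep(0, 2L))
    opt <- adam_init(params)
    history <- numeric(epochs)
    for (epoch in seq_len(epochs)) {
      z1 <- sweep(Z %*% params$W1, 2L, params$b1, "+")
      a1 <- relu(z1)
      logits <- sweep(a1 %*% params$W2, 2L, params$b2, "+")
      p <- softmax_rows(logits)
      history[epoch] <- -mean(log(pmax(p[cbind(seq_len(n), y + 1L)], 1e-12)))
      dlogits <- (p - Y) / n
      grads <- list(W2 = t(a1) %*% dlogits, b2 = colSums(dlogits))
      da1 <- dlogits %*% t(params$W2); da1[z1 <= 0] <- 0
      grads$W1 <- t(Z) %*% da1; grads$b1 <- colSums(da1)
      upd <- adam_step(params, grads, opt, lr = learning_rate)
      params <- upd$params; opt <- upd$state
    }
    structure(list(params = params, latent_dim = d, hidden = as.integer(hidden),
                   history = history),
              class = "fixed_mlp_model")
  })
}

#' @export
predict.fixed_mlp_model <- function(object, newdata, ...) {
  Z <- as.matrix(newdata)
  a1 <- relu(sweep(Z %*% object$params$W1, 2L, object$params$b1, "+"))
  logits <- sweep(a1 %*% object$params$W2, 2L, object$params$b2, "+")
  probs <- softmax_rows(logits)
  colnames(probs) <- c("p_control", "p_asd")
  list(labels = as.integer(probs[, 2L] > probs[, 1L]), probs = probs)
}
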