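# Neural generalized additive model with selected pairwise interactions.
# Each behavioral feature gets its own small subnetwork f_i(x_i); a screened
# set of feature pairs gets bivariate subnetworks f_ij(x_i, x_j); the ASD
# probability is sigmoid(sum of effects + bias). Effects are mean-centered
# over the training set (means absorbed into the bias) so that importance
# scores and partial-dependence curves are identifiable, and low-variance
# effects are pruned to exactly zero.

#' Configuration for the behavioral additive network
#'
#' @param subnet_hidden Widths of the two hidden layers of every subnetwork.
#' @param max_interactions Maximum number of pairwise interaction effects (k).
#' @param l1_penalty L1 penalty on the per-effect output scales.
#' @param prune_threshold Effects whose training-set contribution variance is
#'   below this fraction of the total contribution variance are pruned.
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param seed Integer seed for initialization and batching.
#' @return A `gami_config` list.
#' @export
gami_config <- function(subnet_hidden = c(16L, 16L),
                        max_interactions = 10L,
                        l1_penalty = 1e-4,
                        prune_threshold = 1e-4,
                        epochs = 30L,
                        batch_size = 64L,
                        learning_rate = 1e-3,
                        seed = 1L) {
  stopifnot(length(subnet_hidden) == 2L, all(subnet_hidden >= 1L),
            l1_penalty >= 0, epochs >= 1L, batch_size >= 1L)
  structure(list(subnet_hidden = as.integer(subnet_hidden),
                 max_interactions = as.integer(max_interactions),
                 l1_penalty = l1_penalty,
                 prune_threshold = prune_threshold,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "gami_config")
}

# ---- subnetwork primitives (input dim d -> h1 -> h2 -> 1, ReLU, linear out) --

.subnet_init <- function(d, hidden) {
  h1 <- hidden[1L]; h2 <- hidden[2L]
  list(W1 = he_init(d, h1, fan_in = d), b1 = rep(0, h1),
       W2 = he_init(h1, h2), b2 = rep(0, h2),
       W3 = he_init(h2, 1L), b3 = 0)
}

.subnet_forward <- function(p, x) {
  z1 <- x %*% p$W1
  z1 <- sweep(z1, 2L, p$b1, "+")
  a1 <- relu(z1)
  z2 <- a1 %*% p$W2
  z2 <- sweep(z2, 2L, p$b2, "+")
  a2 <- relu(z2)
  out <- drop(a2 %*% p$W3) + p$b3
  list(out = out, a1 = a1, a2 = a2, z1 = z1, z2 = z2)
}

# Backward pass for one subnetwork given d(loss)/d(out) as a vector.
.subnet_backward <- function(p, x, fwd, dout) {
  da2 <- dout %*% t(p$W3)          # n x h2 (dout is n x 1)
  da2[fwd$z2 <= 0] <- 0
  da1 <- da2 %*% t(p$W2)
  da1[fwd$z1 <= 0] <- 0
  list(W1 = t(x) %*% da1, b1 = colSums(da1),
       W2 = t(fwd$a1) %*% da2, b2 = colSums(da2),
       W3 = t(fwd$a2) %*% dout, b3 = sum(dout))
}

# Train a set of effect subnetworks (plus per-effect scales gamma and a bias)
# against binary cross-entropy on logit = offset + sum_k gamma_k out_k + b.
# `inputs` is a list of n x d matrices, one per effect. Frozen offset allows
# the two-stage fit (interactions trained on top of fixed main effects).
.fit_effect_stage <- function(inputs, y, config, offset = 0, bias_init = 0,
                              stage_seed = 0L) {
  n <- length(y)
  K <- length(inputs)
  with_seed(derive_seed(config$seed, stage_seed), {
    subnets <- lapply(inputs, function(x) .subnet_init(ncol(x), config$subnet_hidden))
    params <- list(gamma = rep(1, K), b = bias_init)
    for (k in seq_len(K)) for (nm in names(subnets[[k]]))
      params[[paste0("s", k, "_", nm)]] <- subnets[[k]][[nm]]
    opt <- adam_init(params)
    history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      batches <- minibatches(n, config$batch_size)
      epoch_loss <- 0
      for (idx in batches) {
        nb <- length(idx)
        fwds <- vector("list", K)
        outs <- matrix(0, nb, max(K, 1L))
        for (k in seq_len(K)) {
          fwds[[k]] <- .subnet_forward(.stage_subnet(params, k), inputs[[k]][idx, , drop = FALSE])
          outs[, k] <- fwds[[k]]$out
        }
        off_b <- if (length(offset) > 1L) offset[idx] else offset
        logit <- off_b + params$b +
          (if (K) drop(outs %*% params$gamma) else 0)
        p_hat <- sigmoid(logit)
        yb <- y[idx]
        epoch_loss <- epoch_loss + bce_loss(p_hat, yb) * nb
        dlogit <- matrix((p_hat - yb) / nb, ncol = 1L)
        grads <- list(gamma = if (K) drop(t(outs) %*% dlogit) +
                        config$l1_penalty * sign(params$gamma) else numeric(0),
                      b = sum(dlogit))
        for (k in seq_len(K)) {
          g <- .subnet_backward(.stage_subnet(params, k),
                                inputs[[k]][idx, , drop = FALSE],
                                fwds[[k]], dlogit * params$gamma[k])
          for (nm in names(g)) grads[[paste0("s", k, "_", nm)]] <- g[[nm]]
        }
        upd <- adam_step(params, grads, opt, lr = config$learning_rate)
        params <- upd$params; opt <- upd$state
      }
      history[epoch] <- epoch_loss / n
    }
    subnets <- lapply(seq_len(K), function(k) .stage_subnet(params, k))
    list(subnets = subnets, gamma = params$gamma, b = params$b, history = history)
  })
}

.stage_subnet <- function(params, k) {
  list(W1 = params[[paste0("s", k, "_W1")]], b1 = params[[paste0("s", k, "_b1")]],
       W2 = params[[paste0("s", k, "_W2")]], b2 = params[[paste0("s", k, "_b2")]],
       W3 = params[[paste0("s", k, "_W3")]], b3 = params[[paste0("s", k, "_b3")]])
}

# ---- interaction screening ----

#' Screen pairwise interactions against main-effect residuals
#'
#' For every candidate feature pair (i, j), a shallow regression tree on
#' (x_i, x_j) is fit to the residuals of the main-effects model, and the pair
#' is scored by the fraction of residual variance explained. The top `k`
#' pairs are returned, ties broken by lexicographic (i, j) order.
#'
#' @param X Feature matrix in [0, 1].
#' @param y 0/1 labels.
#' @param main_model A fitted `gami_model` containing at least main effects
#'   (as returned by [fit_gami()] with `max_interactions = 0`), or any object
#'   with a `gami_predict` method.
#' @param k Maximum number of pairs (k <= 0 gives an empty list).
#' @return Integer matrix with columns `i`, `j` (i < j), at most `k` rows,
#'   ranked by decreasing score; the score is attached as attribute `score`.
#' @export
select_interactions <- function(X, y, main_model, k) {
  if (k <= 0L) return(structure(matrix(integer(0), 0L, 2L,
                                       dimnames = list(NULL, c("i", "j"))),
                                score = numeric(0)))
  p <- ncol(X)
  resid <- y - gami_predict(main_model, X)
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  sst <- sum((resid - mean(resid))^2)
  score <- apply(pairs, 1L, function(pr) {
    df <- data.frame(r = resid, xi = X[, pr[1L]], xj = X[, pr[2L]])
    fit <- rpart::rpart(r ~ xi + xj, data = df, method = "anova",
                        control = rpart::rpart.control(maxdepth = 2L, cp = 0,
                                                       minsplit = 10L, xval = 0L))
    if (sst <= 0) return(0)
    1 - sum((resid - predict(fit, df))^2) / sst
  })
  ord <- order(-score, pairs[, 1L], pairs[, 2L])
  keep <- ord[seq_len(min(k, nrow(pairs)))]
  out <- matrix(as.integer(pairs[keep, , drop = FALSE]), ncol = 2L,
                dimnames = list(NULL, c("i", "j")))
  structure(out, score = score[keep])
}

# ---- full three-stage fit ----

#' Fit the behavioral additive-interaction network
#'
#' Three-stage fit: (1) univariate main-effect subnetworks trained with
#' binary cross-entropy plus an L1 penalty on the effect-output scales;
#' (2) interaction screening on the main-effect residuals
#' ([select_interactions()]); (3) bivariate interaction subnetworks trained
#' on top of the frozen main effects. Effects with negligible training-set
#' contribution variance are pruned to exactly zero, and active effects are
#' mean-centered with the means absorbed into the bias.
#'
#' @param X Feature matrix (subjects x features) with values in [0, 1].
#' @param y 0/1 labels (both classes required).
#' @param config A [gami_config()].
#' @return A `gami_model`.
#' @export
fit_gami <- function(X, y, config = gami_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (min(X, na.rm = TRUE) < -1e-8 || max(X, na.rm = TRUE) > 1 + 1e-8)
    stop("X must be scaled to [0, 1] (run the preprocessor first)")
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  p <- ncol(X)
  feature_names <- colnames(X) %||% sprintf("x%d", seq_len(p))
  colnames(X) <- feature_names
  if (config$max_interactions > p * (p - 1L) / 2L)
    config$max_interactions <- as.integer(p * (p - 1L) / 2L)

  # stage 1: main effects
  main_inputs <- lapply(seq_len(p), function(i) X[, i, drop = FALSE])
  s1 <- .fit_effect_stage(main_inputs, y, config, stage_seed = 1L)

  model <- structure(list(
    feature_names = feature_names, p = p,
    main_subnets = s1$subnets, main_gamma = s1$gamma,
    pairs = matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))),
    inter_subnets = list(), inter_gamma = numeric(0),
    bias = s1$b,
    main_mask = rep(TRUE, p), inter_mask = logical(0),
    main_centers = rep(0, p), inter_centers = numeric(0),
    config = config,
    history = list(main = s1$history, interaction = numeric(0)),
    interaction_scores = numeric(0)
  ), class = "gami_model")

  # stage 2 + 3: interactions on residual signal
  if (config$max_interactions > 0L) {
    L <- select_interactions(X, y, model, config$max_interactions)
    if (nrow(L)) {
      main_logit <- .gami_raw_logit(model, X)
      inter_inputs <- lapply(seq_len(nrow(L)), function(q)
        X[, c(L[q, 1L], L[q, 2L]), drop = FALSE])
      s3 <- .fit_effect_stage(inter_inputs, y, config,
                              offset = main_logit - model$bias,
                              bias_init = model$bias, stage_seed = 3L)
      model$pairs <- L
      model$inter_subnets <- s3$subnets
      model$inter_gamma <- s3$gamma
      model$inter_mask <- rep(TRUE, nrow(L))
      model$inter_centers <- rep(0, nrow(L))
      model$bias <- s3$b
      model$history$interaction <- s3$history
      model$interaction_scores <- attr(L, "score")
    }
  }

  # prune low-variance effects, then center the survivors
  contrib <- .gami_raw_contributions(model, X)
  v <- apply(contrib, 2L, var)
  total <- sum(v)
  active <- if (total > 0) v >= config$prune_threshold * total else rep(FALSE, length(v))
  model$main_mask <- active[seq_len(p)]
  if (nrow(model$pairs)) model$inter_mask <- active[p + seq_len(nrow(model$pairs))]
  centers <- colMeans(contrib) * active
  model$main_centers <- centers[seq_len(p)]
  if (nrow(model$pairs)) model$inter_centers <- centers[p + seq_len(nrow(model$pairs))]
  model$bias <- model$bias + sum(centers)
  model
}

# Raw (uncentered, unmasked) per-effect contributions, mains then interactions.
.gami_raw_contributions <- function(model, X) {
  p <- model$p
  q <- nrow(model$pairs)
  out <- matrix(0, nrow(X), p + q)
  for (i in seq_len(p)) {
    out[, i] <- model$main_gamma[i] *
      .subnet_forward(model$main_subnets[[i]], X[, i, drop = FALSE])$out
  }
  for (j in seq_len(q)) {
    xi <- X[, c(model$pairs[j, 1L], model$pairs[j, 2L]), drop = FALSE]
    out[, p + j] <- model$inter_gamma[j] *
      .subnet_forward(model$inter_subnets[[j]], xi)$out
  }
  out
}

.gami_raw_logit <- function(model, X) {
  contrib <- .gami_raw_contributions(model, X)
  mask <- c(model$main_mask, model$inter_mask)
  centers <- c(model$main_centers, model$inter_centers)
  drop(contrib %*% mask) - sum(centers[mask]) + model$bias
}

#' Per-subject effect contributions
#'
#' One column per active (unpruned) effect; main-effect columns are named by
#' feature, interaction columns `"a:b"`. The row sums plus the model bias,
#' passed through the sigmoid, reproduce [gami_predict()] exactly.
#'
#' @param model A `gami_model`.
#' @param X Feature matrix with the fitted feature count.
#' @return Numeric matrix (subjects x active effects).
#' @export
gami_effects <- function(model, X) {
  X <- .gami_check_X(model, X)
  contrib <- .gami_raw_contributions(model, X)
  centers <- c(model$main_centers, model$inter_centers)
  contrib <- sweep(contrib, 2L, centers)
  nm <- c(model$feature_names,
          if (nrow(model$pairs)) paste(model$feature_names[model$pairs[, 1L]],
                                       model$feature_names[model$pairs[, 2L]],
                                       sep = ":") else character(0))
  colnames(contrib) <- nm
  mask <- c(model$main_mask, model$inter_mask)
  contrib[, mask, drop = FALSE]
}

#' Predict ASD probability from the behavioral model
#'
#' @param model A `gami_model`.
#' @param X Feature matrix with the fitted feature count, values in [0, 1].
#' @return Numeric vector of probabilities in [0, 1] (the behavioral
#'   embedding forwarded to the fusion stage).
#' @export
gami_predict <- function(model, X) {
  X <- .gami_check_X(model, X)
  eff <- gami_effects(model, X)
  prob <- sigmoid((if (ncol(eff)) rowSums(eff) else rep(0, nrow(X))) + model$bias)
  names(prob) <- rownames(X)
  prob
}

.gami_check_X <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$p)
    stop("X has ", ncol(X), " features; model was fitted on ", model$p)
  X
}

#' Effect importance ranking
#'
#' Importance of an active effect is the variance of its contribution over
#' `X`, normalized so the scores sum to 1. Descending order, ties broken by
#' effect name.
#'
#' @param model A `gami_model`.
#' @param X Feature matrix (typically the training set).
#' @return data.frame with columns `effect`, `score`; zero rows if every
#'   effect was pruned.
#' @export
gami_importance <- function(model, X) {
  eff <- gami_effects(model, X)
  if (!ncol(eff)) return(data.frame(effect = character(0), score = numeric(0)))
  v <- apply(eff, 2L, var)
  score <- if (sum(v) > 0) v / sum(v) else rep(1 / length(v), length(v))
  ord <- order(-score, colnames(eff))
  data.frame(effect = colnames(eff)[ord], score = unname(score[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top features implicated by the effect ranking
#'
#' Scans the ranked effect list from [gami_importance()] and collects the
#' distinct features involved (an interaction effect names both of its
#' features), stopping after `n` features.
#'
#' @param model A `gami_model`.
#' @param X Feature matrix.
#' @param n Number of features to return.
#' @return Character vector of at most `n` feature names, most important
#'   first.
#' @export
gami_top_features <- function(model, X, n = 5L) {
  imp <- gami_importance(model, X)
  feats <- character(0)
  for (eff in imp$effect) {
    for (f in strsplit(eff, ":", fixed = TRUE)[[1L]]) {
      if (!(f %in% feats)) feats <- c(feats, f)
      if (length(feats) >= n) return(feats)
    }
  }
  feats
}

#' Partial-dependence curve of a main effect
#'
#' Because the model is additive, the curve is exactly the univariate
#' subnetwork's (centered, scaled) output on the grid - no averaging over the
#' data distribution is needed.
#'
#' @param model A `gami_model`.
#' @param feature Feature index or name; must be an active main effect.
#' @param grid Numeric grid in [0, 1].
#' @return data.frame with columns `grid`, `effect`.
#' @export
gami_partial_dependence <- function(model, feature,
                                    grid = seq(0, 1, length.out = 50L)) {
  if (is.character(feature)) feature <- match(feature, model$feature_names)
  if (is.na(feature) || feature < 1L || feature > model$p)
    stop("unknown feature")
  if (!model$main_mask[feature])
    stop("feature '", model$feature_names[feature],
         "' was pruned; no active main effect to evaluate")
  g <- matrix(grid, ncol = 1L)
  val <- model$main_gamma[feature] *
    .subnet_forward(model$main_subnets[[feature]], g)$out -
    model$main_centers[feature]
  data.frame(grid = grid, effect = val)
}

#' @export
print.gami_model <- function(x, ...) {
  cat("Behavioral additive-interaction network\n")
  cat("  features:", x$p, "| active main effects:", sum(x$main_mask), "\n")
  cat("  interaction pairs:", nrow(x$pairs),
      "| active:", sum(x$inter_mask), "\n")
  cat("  bias:", format(x$bias, digits = 4), "\n")
  if (length(x$history$main))
    cat("  final training BCE:", format(tail_value(x$history$main), digits = 4), "\n")
  invisible(x)
}

tail_value <- function(x) x[length(x)]
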