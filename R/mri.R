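# Hybrid CNN-GNN structural-MRI encoder. A small stack of 3x3x3
# convolutions (stride 1, zero padding, so atlas masks still align) extracts
# volumetric features; features are mean-pooled inside each atlas region to
# form graph nodes; two symmetric-normalized graph-convolution layers
# propagate node features over the anatomical-adjacency graph; the flattened
# node embeddings are mapped linearly to a fixed-length embedding. Training
# is end-to-end with a temporary linear classification head (binary
# cross-entropy), discarded after fitting.

#' Configuration for the MRI encoder
#'
#' @param conv_channels Channel counts of the convolutional blocks.
#' @param gnn_layers Number of graph-convolution layers.
#' @param gnn_hidden Width of each graph-convolution layer.
#' @param embed_dim Length of the output embedding (8..1024; default 128).
#' @param dropout Dropout rate applied to the flattened node embeddings
#'   during training.
#' @param epochs,learning_rate,batch_size Adam training schedule.
#' @param pool_input `"cnn"` pools the convolutional feature maps (default);
#'   `"raw"` pools raw voxel intensities instead.
#' @param seed Integer seed.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(conv_channels = c(8L, 16L),
                           gnn_layers = 2L,
                           gnn_hidden = 32L,
                           embed_dim = 128L,
                           dropout = 0.2,
                           epochs = 30L,
                           learning_rate = 1e-3,
                           batch_size = 16L,
                           pool_input = c("cnn", "raw"),
                           seed = 1L) {
  stopifnot(length(conv_channels) == 2L, all(conv_channels >= 1L),
            gnn_layers == 2L, gnn_hidden >= 1L,
            embed_dim >= 8L, embed_dim <= 1024L,
            dropout >= 0, dropout < 1)
  structure(list(conv_channels = as.integer(conv_channels),
                 gnn_layers = as.integer(gnn_layers),
                 gnn_hidden = as.integer(gnn_hidden),
                 embed_dim = as.integer(embed_dim),
                 dropout = dropout,
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 pool_input = match.arg(pool_input),
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Anatomical adjacency of atlas regions
#'
#' Two regions are adjacent iff some voxel of one shares a face
#' (6-connectivity) with a voxel of the other.
#'
#' @param atlas Integer 3D label volume (0 = background).
#' @return Symmetric 0/1 matrix with zero diagonal; rows/columns ordered by
#'   ascending label, dimnames set to the labels.
#' @export
atlas_adjacency <- function(atlas) {
  labels <- sort(unique(as.integer(atlas[atlas > 0])))
  R <- length(labels)
  if (R < 2L) stop("atlas must contain at least 2 labelled regions")
  d <- dim(atlas)
  A <- matrix(0L, R, R, dimnames = list(labels, labels))
  idx <- stats::setNames(seq_len(R), labels)
  pair_up <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    if (!any(keep)) return(NULL)
    cbind(idx[as.character(a[keep])], idx[as.character(b[keep])])
  }
  shifts <- list(
    pair_up(atlas[-d[1], , ], atlas[-1, , ]),
    pair_up(atlas[, -d[2], ], atlas[, -1, ]),
    pair_up(atlas[, , -d[3]], atlas[, , -1])
  )
  for (pr in shifts) {
    if (is.null(pr)) next
    A[pr] <- 1L
    A[pr[, 2:1, drop = FALSE]] <- 1L
  }
  A
}

#' Symmetric-normalized propagation operator
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)` where `D` is the degree matrix of
#' `A + I` - the propagation operator used by each graph-convolution layer.
#'
#' @param A Symmetric 0/1 adjacency with zero diagonal.
#' @return Symmetric matrix of the same dimension.
#' @export
normalized_adjacency <- function(A) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A))
  Ai <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Ai))
  Ai * (dinv %o% dinv)
}

# Row-normalized pooling matrix: P[r, v] = 1/|region r| if atlas[v] == label r.
.pooling_matrix <- function(atlas, labels) {
  V <- length(atlas)
  P <- matrix(0, length(labels), V)
  av <- as.integer(atlas)
  for (r in seq_along(labels)) {
    vox <- which(av == labels[r])
    if (!length(vox)) stop("atlas region ", labels[r], " has no voxels")
    P[r, vox] <- 1 / length(vox)
  }
  P
}

#' Mean-pool a feature volume inside each atlas region
#'
#' @param features Array of shape `c(dim(atlas), C)` (or `dim(atlas)` for a
#'   single channel), spatially aligned with the atlas.
#' @param atlas Integer label volume.
#' @param labels Optional label set to pool over (ascending); defaults to the
#'   labels present. A requested label with no voxels is an error.
#' @return Matrix (regions x channels), rows in ascending label order.
#' @export
roi_pool <- function(features, atlas, labels = NULL) {
  d <- dim(atlas)
  features <- as.array(features)
  fd <- dim(features)
  if (length(fd) == 3L) fd <- c(fd, 1L)
  if (!all(fd[1:3] == d)) stop("feature volume and atlas shapes differ")
  C <- fd[4L]
  F <- matrix(features, prod(d), C)
  if (is.null(labels)) labels <- sort(unique(as.integer(atlas[atlas > 0])))
  P <- .pooling_matrix(atlas, labels)
  out <- P %*% F
  rownames(out) <- labels
  out
}

# ---- parameter containers and forward passes ----

.mri_init_params <- function(config, R) {
  C1 <- config$conv_channels[1L]; C2 <- config$conv_channels[2L]
  H <- config$gnn_hidden; D <- config$embed_dim
  Cin2 <- if (config$pool_input == "cnn") C2 else 1L
  p <- list(
    Wc1 = he_init(27L, C1, fan_in = 27L), bc1 = rep(0, C1),
    Wc2 = he_init(27L * C1, C2), bc2 = rep(0, C2),
    Wg1 = he_init(Cin2, H, fan_in = Cin2), bg1 = rep(0, H),
    Wg2 = he_init(H, H), bg2 = rep(0, H),
    Wr = he_init(R * H, D), br = rep(0, D),
    Wh = matrix(rnorm(D, sd = 0.05), D, 1L), bh = 0
  )
  p
}

# Convolutional feature maps for one subject volume: V x C2 matrix plus the
# intermediates needed for backprop.
.cnn_forward <- function(params, vol, dims) {
  X0 <- matrix(as.numeric(vol), ncol = 1L)
  Xcol1 <- im2col3(X0, dims)
  Z1 <- sweep(Xcol1 %*% params$Wc1, 2L, params$bc1, "+")
  F1 <- relu(Z1)
  Xcol2 <- im2col3(F1, dims)
  Z2 <- sweep(Xcol2 %*% params$Wc2, 2L, params$bc2, "+")
  F2 <- relu(Z2)
  list(Xcol1 = Xcol1, Z1 = Z1, F1 = F1, Xcol2 = Xcol2, Z2 = Z2, F2 = F2)
}

# GNN + readout for one subject given pooled node features N (R x C).
.gnn_forward <- function(params, N, Ahat) {
  M1 <- Ahat %*% N
  Zg1 <- sweep(M1 %*% params$Wg1, 2L, params$bg1, "+")
  G1 <- relu(Zg1)
  M2 <- Ahat %*% G1
  Zg2 <- sweep(M2 %*% params$Wg2, 2L, params$bg2, "+")
  G2 <- relu(Zg2)
  flat <- as.numeric(G2)          # column-major; node order = ascending label
  emb <- drop(crossprod(params$Wr, flat)) + params$br
  list(M1 = M1, Zg1 = Zg1, G1 = G1, M2 = M2, Zg2 = Zg2, G2 = G2,
       flat = flat, emb = emb)
}

#' Convolutional feature maps of a volume
#'
#' Runs the fitted (or freshly initialized) convolutional blocks on a single
#' volume, preserving the spatial grid so atlas masks still apply.
#'
#' @param volume 3D array matching the encoder's training shape.
#' @param encoder An `mri_encoder` from [fit_mri_encoder()].
#' @return Array of shape `c(dim(volume), C)` with `C` the final channel
#'   count.
#' @export
cnn_features <- function(volume, encoder) {
  d <- encoder$dims
  if (!all(dim(volume) == d)) stop("volume shape differs from the training shape")
  f <- .cnn_forward(encoder$params, volume, d)
  array(f$F2, dim = c(d, ncol(f$F2)))
}

#' Graph embedding of an ROI graph
#'
#' Applies the fitted graph-convolution layers and linear readout to a graph
#' of pooled node features.
#'
#' @param graph List with `node_features` (regions x channels, ascending
#'   label order) and `adjacency` (symmetric 0/1, zero diagonal).
#' @param encoder An `mri_encoder`.
#' @return Numeric embedding of length `embed_dim`.
#' @export
gnn_embed <- function(graph, encoder) {
  N <- as.matrix(graph$node_features)
  if (nrow(N) != encoder$n_regions)
    stop("graph has ", nrow(N), " regions; encoder was fitted with ",
         encoder$n_regions)
  Ahat <- normalized_adjacency(graph$adjacency)
  .gnn_forward(encoder$params, N, Ahat)$emb
}

#' Fit the CNN-GNN encoder on labelled volumes
#'
#' End-to-end training of convolutional blocks, graph convolutions and
#' readout with a temporary linear head (binary cross-entropy, Adam); the
#' head is discarded and only the embedding network is kept.
#'
#' @param volumes List of 3D arrays sharing one shape, or a 4D array with
#'   subjects in the last dimension.
#' @param atlas Integer label volume of the same spatial shape.
#' @param labels 0/1 class labels, one per subject (both classes required).
#' @param config An [encoder_config()].
#' @return An `mri_encoder` with elements `params`, `config`, `dims`,
#'   `roi_labels`, `adjacency`, and training `history` (mean BCE per epoch).
#' @export
fit_mri_encoder <- function(volumes, atlas, labels, config = encoder_config()) {
  volumes <- .as_volume_list(volumes)
  n <- length(volumes)
  y <- as.integer(labels)
  stopifnot(length(y) == n)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  d <- dim(atlas)
  if (!all(dim(volumes[[1L]]) == d)) stop("volume and atlas shapes differ")

  roi_labels <- sort(unique(as.integer(atlas[atlas > 0])))
  R <- length(roi_labels)
  if (R < 2L) stop("atlas must contain at least 2 regions")
  A <- atlas_adjacency(atlas)
  Ahat <- normalized_adjacency(A)
  P <- .pooling_matrix(atlas, roi_labels)
  H <- config$gnn_hidden

  with_seed(config$seed, {
    params <- .mri_init_params(config, R)
    opt <- adam_init(params)
    history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      batches <- minibatches(n, config$batch_size)
      epoch_loss <- 0
      for (idx in batches) {
        B <- length(idx)
        step <- .mri_batch_step(params, volumes[idx], y[idx], d, P, Ahat, config)
        epoch_loss <- epoch_loss + step$loss * B
        upd <- adam_step(params, step$grads, opt, lr = config$learning_rate)
        params <- upd$params; opt <- upd$state
      }
      history[epoch] <- epoch_loss / n
    }
    params$Wh <- NULL; params$bh <- NULL   # discard the temporary head
    structure(list(params = params, config = config, dims = d,
                   roi_labels = roi_labels, n_regions = R,
                   adjacency = A, pool = P, history = history),
              class = "mri_encoder")
  })
}

# One forward/backward pass over a minibatch; returns mean BCE and gradients.
# All subjects are stacked row-wise into (B*V) x C matrices so the expensive
# convolution products run as single BLAS calls.
.mri_batch_step <- function(params, vols, yb, dims, P, Ahat, config) {
  B <- length(vols)
  V <- prod(dims)
  R <- nrow(P); H <- config$gnn_hidden; D <- config$embed_dim
  use_cnn <- config$pool_input == "cnn"

  X0 <- matrix(unlist(vols, use.names = FALSE), ncol = 1L)
  if (use_cnn) {
    Xcol1 <- im2col3(X0, dims, B)
    Z1 <- sweep(Xcol1 %*% params$Wc1, 2L, params$bc1, "+")
    F1 <- relu(Z1)
    Xcol2 <- im2col3(F1, dims, B)
    Z2 <- sweep(Xcol2 %*% params$Wc2, 2L, params$bc2, "+")
    F2 <- relu(Z2)
  } else {
    F2 <- X0
  }
  rows_of <- function(s) (s - 1L) * V + seq_len(V)
  Ns <- lapply(seq_len(B), function(s) P %*% F2[rows_of(s), , drop = FALSE])
  gnn <- lapply(Ns, function(N) .gnn_forward(params, N, Ahat))
  FLAT <- do.call(rbind, lapply(gnn, `[[`, "flat"))      # B x (R*H)
  keep <- if (config$dropout > 0)
    matrix(runif(B * ncol(FLAT)) >= config$dropout, B) / (1 - config$dropout)
  else matrix(1, B, ncol(FLAT))
  FLATd <- FLAT * keep
  EMB <- sweep(FLATd %*% params$Wr, 2L, params$br, "+")  # B x D
  logit <- drop(EMB %*% params$Wh) + params$bh
  p_hat <- sigmoid(logit)
  loss <- bce_loss(p_hat, yb)

  dlogit <- matrix((p_hat - yb) / B, ncol = 1L)
  grads <- list(Wh = crossprod(EMB, dlogit), bh = sum(dlogit))
  dEMB <- tcrossprod(dlogit, params$Wh)
  grads$Wr <- crossprod(FLATd, dEMB)
  grads$br <- colSums(dEMB)
  dFLAT <- tcrossprod(dEMB, params$Wr) * keep

  grads$Wg1 <- params$Wg1 * 0; grads$bg1 <- rep(0, H)
  grads$Wg2 <- matrix(0, H, H); grads$bg2 <- rep(0, H)
  dF2 <- matrix(0, nrow(F2), ncol(F2))
  for (s in seq_len(B)) {
    g <- gnn[[s]]
    dG2 <- matrix(dFLAT[s, ], R, H)
    dZg2 <- dG2 * (g$Zg2 > 0)
    grads$Wg2 <- grads$Wg2 + crossprod(g$M2, dZg2)
    grads$bg2 <- grads$bg2 + colSums(dZg2)
    dG1 <- tcrossprod(Ahat %*% dZg2, params$Wg2)
    dZg1 <- dG1 * (g$Zg1 > 0)
    grads$Wg1 <- grads$Wg1 + crossprod(g$M1, dZg1)
    grads$bg1 <- grads$bg1 + colSums(dZg1)
    dN <- tcrossprod(Ahat %*% dZg1, params$Wg1)
    dF2[rows_of(s), ] <- crossprod(P, dN)
  }

  if (use_cnn) {
    dZ2 <- dF2 * (Z2 > 0)
    grads$Wc2 <- crossprod(Xcol2, dZ2)
    grads$bc2 <- colSums(dZ2)
    dF1 <- col2im3(tcrossprod(dZ2, params$Wc2), dims, B)
    dZ1 <- dF1 * (Z1 > 0)
    grads$Wc1 <- crossprod(Xcol1, dZ1)
    grads$bc1 <- colSums(dZ1)
  } else {
    grads$Wc1 <- params$Wc1 * 0; grads$bc1 <- params$bc1 * 0
    grads$Wc2 <- params$Wc2 * 0; grads$bc2 <- params$bc2 * 0
  }
  list(loss = loss, grads = grads)
}

#' Embed volumes with a fitted encoder
#'
#' Deterministic evaluation-mode forward pass (no dropout, no head).
#'
#' @param encoder An `mri_encoder`.
#' @param volumes List of 3D arrays (or 4D array) matching the training
#'   shape; names are carried to rownames.
#' @return Matrix (subjects x `embed_dim`).
#' @export
mri_embed <- function(encoder, volumes) {
  volumes <- .as_volume_list(volumes)
  d <- encoder$dims
  Ahat <- normalized_adjacency(encoder$adjacency)
  P <- encoder$pool
  out <- t(vapply(volumes, function(v) {
    if (!all(dim(v) == d)) stop("volume shape differs from the training shape")
    F2 <- if (encoder$config$pool_input == "cnn")
      .cnn_forward(encoder$params, v, d)$F2
    else matrix(as.numeric(v), ncol = 1L)
    .gnn_forward(encoder$params, P %*% F2, Ahat)$emb
  }, numeric(encoder$config$embed_dim)))
  rownames(out) <- names(volumes)
  out
}

.as_volume_list <- function(volumes) {
  if (is.array(volumes) && length(dim(volumes)) == 4L) {
    n <- dim(volumes)[4L]
    volumes <- lapply(seq_len(n), function(i) volumes[, , , i])
  }
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  volumes
}

#' @export
print.mri_encoder <- function(x, ...) {
  cat("Hybrid CNN-GNN MRI encoder\n")
  cat("  volume shape:", paste(x$dims, collapse = "x"),
      "| regions:", x$n_regions, "\n")
  cat("  conv channels:", paste(x$config$conv_channels, collapse = ", "),
      "| gnn hidden:", x$config$gnn_hidden,
      "| embedding dim:", x$config$embed_dim, "\n")
  cat("  final training BCE:", format(tail_value(x$history), digits = 4), "\n")
  invisible(x)
}
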