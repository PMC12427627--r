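# Synthetic multimodal cohort generator: class-shifted behavioral features
# with missingness, plus 3D volumes carrying an intensity shift inside a
# subset of atlas regions. Every downstream stage is testable on its output.

#' Generate a toy brain atlas as a regular grid partition
#'
#' Partitions a 3D volume into `n_rois` spatially contiguous rectangular
#' blocks, labelled `1..n_rois`. The partition is deterministic: the number of
#' cuts along each axis is the factorization of `n_rois` that best balances
#' block shape (exact-division factorizations preferred, ties broken
#' lexicographically), so the resulting region adjacency has a known closed
#' form for testing.
#'
#' @param shape Integer vector of length 3, the volume dimensions (each >= 4).
#' @param n_rois Number of regions, at least 2 and at most the voxel count.
#' @param seed Unused for the partition itself (it is deterministic); kept so
#'   the call signature matches the other generators.
#' @return Integer 3D array with values in `1..n_rois` (no background voxels).
#' @export
generate_toy_atlas <- function(shape, n_rois, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L))
  n_rois <- as.integer(n_rois)
  if (n_rois < 2L) stop("n_rois must be at least 2")
  if (n_rois > prod(shape)) stop("n_rois exceeds the voxel count")
  f <- .grid_factorization(n_rois, shape)
  if (is.null(f)) {
    stop("n_rois = ", n_rois, " cannot be partitioned into contiguous blocks ",
         "for shape ", paste(shape, collapse = "x"))
  }
  cuts <- lapply(1:3, function(ax) {
    # near-equal contiguous slabs along the axis
    bounds <- round(seq(0, shape[ax], length.out = f[ax] + 1L))
    rep(seq_len(f[ax]), times = diff(bounds))
  })
  atlas <- array(0L, dim = shape)
  ix <- cuts[[1L]]; iy <- cuts[[2L]]; iz <- cuts[[3L]]
  for (z in seq_len(shape[3])) for (y in seq_len(shape[2])) {
    atlas[, y, z] <- (iz[z] - 1L) * f[1L] * f[2L] + (iy[y] - 1L) * f[1L] + ix
  }
  atlas
}

# Best axis factorization of n into 3 factors f with f[i] <= shape[i].
# Prefer factorizations where every axis divides exactly; then minimize the
# spread of block edge lengths; ties broken by lexicographic order of f.
.grid_factorization <- function(n, shape) {
  best <- NULL
  best_key <- NULL
  for (f1 in 1:min(n, shape[1])) {
    if (n %% f1 != 0L) next
    n2 <- n %/% f1
    for (f2 in 1:min(n2, shape[2])) {
      if (n2 %% f2 != 0L) next
      f3 <- n2 %/% f2
      if (f3 > shape[3]) next
      exact <- all(shape %% c(f1, f2, f3) == 0L)
      edges <- shape / c(f1, f2, f3)
      key <- c(!exact, stats::var(edges), f1, f2, f3)
      if (is.null(best_key) || .lex_less(key, best_key)) {
        best <- c(f1, f2, f3)
        best_key <- key
      }
    }
  }
  best
}

.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Generate a synthetic multimodal cohort
#'
#' Draws a cohort of `n` subjects with balanced classes (Control = 0,
#' ASD = 1). Behavioral features are standard-normal noise; for class-1
#' subjects the chosen informative features have their mean shifted by
#' `behavioral_effect`. Volumes are unit-variance Gaussian noise; for class-1
#' subjects the mean intensity inside the informative atlas regions is
#' shifted by `roi_effect`. Missing cells are inserted completely at random
#' into the behavioral table at rate `missing_rate`. The seed fully
#' determines the cohort: regeneration is bit-identical.
#'
#' @param n Number of subjects (>= 4; classes balanced to within 1).
#' @param n_features Number of behavioral features.
#' @param behavioral_effect Mean shift (in SD units) added to informative
#'   behavioral features for class-1 subjects.
#' @param n_informative_features How many behavioral features carry the shift.
#' @param roi_effect Mean intensity shift inside informative regions for
#'   class-1 subjects.
#' @param informative_rois How many atlas regions carry the shift.
#' @param shape 3D volume dimensions.
#' @param n_rois Number of atlas regions.
#' @param missing_rate Fraction of behavioral cells set missing, in [0, 1).
#' @param seed Integer seed.
#' @return An object of class `synthetic_cohort`: list with `behavioral`
#'   (data.frame with `SUBJ_ID`, feature columns, `DX_GROUP` coded 1 = Control,
#'   2 = ASD), `volumes` (list of 3D arrays), `atlas`, `labels` (0/1 vector
#'   named by subject id), and `truth` (informative indices, effects, seed).
#' @export
generate_cohort <- function(n, n_features,
                            behavioral_effect = 0,
                            n_informative_features = 0,
                            roi_effect = 0,
                            informative_rois = 0,
                            shape = c(8L, 8L, 8L),
                            n_rois = 8L,
                            missing_rate = 0,
                            seed = 1L) {
  stopifnot(n >= 4L, n_features >= 1L)
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (n_informative_features > n_features)
    stop("n_informative_features exceeds n_features")
  if (informative_rois > n_rois) stop("informative_rois exceeds n_rois")

  atlas <- generate_toy_atlas(shape, n_rois, seed)
  with_seed(seed, {
    labels <- sample(rep(c(0L, 1L), length.out = n))
    ids <- sprintf("S%04d", seq_len(n))
    names(labels) <- ids

    inf_feats <- if (n_informative_features > 0)
      sort(sample.int(n_features, n_informative_features)) else integer(0)
    inf_rois <- if (informative_rois > 0)
      sort(sample.int(n_rois, informative_rois)) else integer(0)

    X <- matrix(rnorm(n * n_features), n, n_features)
    if (length(inf_feats))
      X[labels == 1L, inf_feats] <- X[labels == 1L, inf_feats] + behavioral_effect
    if (missing_rate > 0) {
      miss <- runif(n * n_features) < missing_rate
      X[miss] <- NA_real_
    }

    roi_mask <- array(atlas %in% inf_rois, dim = shape)
    nvox <- prod(shape)
    volumes <- lapply(seq_len(n), function(i) {
      v <- array(rnorm(nvox), dim = shape)
      if (labels[i] == 1L && length(inf_rois)) v[roi_mask] <- v[roi_mask] + roi_effect
      v
    })
    names(volumes) <- ids

    behavioral <- data.frame(SUBJ_ID = ids, X, stringsAsFactors = FALSE)
    colnames(behavioral) <- c("SUBJ_ID", sprintf("FEAT_%02d", seq_len(n_features)))
    behavioral$DX_GROUP <- labels + 1L  # 1 = Control, 2 = ASD

    structure(list(
      behavioral = behavioral,
      volumes = volumes,
      atlas = atlas,
      labels = labels,
      truth = list(
        informative_features = inf_feats,
        informative_rois = inf_rois,
        behavioral_effect = behavioral_effect,
        roi_effect = roi_effect,
        missing_rate = missing_rate,
        seed = as.integer(seed)
      )
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic multimodal cohort\n")
  cat("  subjects:", length(x$labels),
      sprintf("(%d Control / %d ASD)\n", sum(x$labels == 0), sum(x$labels == 1)))
  cat("  behavioral features:", ncol(x$behavioral) - 2L, "\n")
  cat("  volume shape:", paste(dim(x$atlas), collapse = "x"),
      "| atlas regions:", max(x$atlas), "\n")
  cat("  informative features:", length(x$truth$informative_features),
      "| informative regions:", length(x$truth$informative_rois), "\n")
  invisible(x)
}

#' Write a cohort to disk (CSV + NIfTI + JSON truth record)
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$behavioral, file.path(dir, "behavioral.csv"), row.names = FALSE)
  RNifti::writeNifti(cohort$atlas, file.path(dir, "atlas.nii.gz"))
  vdir <- file.path(dir, "volumes")
  dir.create(vdir, showWarnings = FALSE)
  for (id in names(cohort$volumes)) {
    RNifti::writeNifti(cohort$volumes[[id]], file.path(vdir, paste0(id, ".nii.gz")))
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A `synthetic_cohort`.
#' @export
read_cohort <- function(dir) {
  behavioral <- read.csv(file.path(dir, "behavioral.csv"), stringsAsFactors = FALSE)
  atlas <- array(as.integer(round(RNifti::readNifti(file.path(dir, "atlas.nii.gz")))),
                 dim = dim(RNifti::readNifti(file.path(dir, "atlas.nii.gz"))))
  vfiles <- list.files(file.path(dir, "volumes"), pattern = "\\.nii(\\.gz)?$",
                       full.names = TRUE)
  volumes <- lapply(vfiles, function(f) {
    v <- RNifti::readNifti(f)
    array(as.numeric(v), dim = dim(v))
  })
  names(volumes) <- sub("\\.nii(\\.gz)?$", "", basename(vfiles))
  labels <- as.vector(encode_labels(behavioral$DX_GROUP))
  names(labels) <- behavioral$SUBJ_ID
  truth_file <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_file)) jsonlite::read_json(truth_file, simplifyVector = TRUE) else NULL
  structure(list(behavioral = behavioral, volumes = volumes[behavioral$SUBJ_ID],
                 atlas = atlas, labels = labels, truth = truth),
            class = "synthetic_cohort")
}
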