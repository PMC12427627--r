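# Leakage-safe behavioral preprocessing: identifier dropping, median
# imputation, categorical label-encoding, min-max scaling to [0, 1], label
# extraction, and cross-modality subject alignment. All statistics are
# computed by `fit_preprocessor` on the data it is given (typically the
# training split) and reused verbatim by `apply_preprocessor`.

#' Fit preprocessing state on a raw behavioral table
#'
#' Computes, per feature column: the median of observed values (numeric
#' columns), an alphabetical label -> integer map (categorical columns), and
#' the post-imputation min/max used for scaling. Identifier and label columns
#' are dropped from the feature set.
#'
#' @param table A data.frame; missing cells as `NA` (empty strings in
#'   character columns are treated as missing).
#' @param id_columns Column names dropped as identifiers. Names absent from
#'   the table are ignored with a warning.
#' @param label_column Name of the diagnosis column to exclude from features
#'   (kept for [encode_labels()]); `NULL` if none.
#' @return A `preprocessor_state` object.
#' @export
fit_preprocessor <- function(table,
                             id_columns = c("SUBJ_ID", "ID", "Participant_ID", "Name"),
                             label_column = "DX_GROUP") {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  present <- id_columns[id_columns %in% names(table)]
  if (!missing(id_columns) && length(setdiff(id_columns, names(table)))) {
    warning("ignoring absent id columns: ",
            paste(setdiff(id_columns, names(table)), collapse = ", "))
  }
  drop <- c(present, intersect(label_column, names(table)))
  feats <- setdiff(names(table), drop)
  if (!length(feats)) stop("no feature columns remain after dropping identifiers")

  medians <- list(); category_maps <- list()
  mins <- numeric(0); maxs <- numeric(0)
  for (col in feats) {
    x <- table[[col]]
    if (is.numeric(x)) {
      obs <- x[!is.na(x)]
      if (!length(obs)) stop("column '", col, "' has no observed numeric values")
      medians[[col]] <- median(obs)
      x[is.na(x)] <- medians[[col]]
    } else {
      x <- as.character(x)
      x[!is.na(x) & x == ""] <- NA_character_
      obs <- x[!is.na(x)]
      if (!length(obs)) stop("column '", col, "' has no observed values")
      levels <- sort(unique(obs))
      map <- stats::setNames(seq_along(levels) - 1L, levels)
      category_maps[[col]] <- map
      mode_level <- names(which.max(table(factor(obs, levels = levels))))
      medians[[col]] <- mode_level  # imputation value for categoricals: mode
      x[is.na(x)] <- mode_level
      x <- unname(map[x])
    }
    mins[col] <- min(x)
    maxs[col] <- max(x)
  }
  structure(list(
    id_columns = present,
    label_column = label_column,
    feature_order = feats,
    medians = medians,
    category_maps = category_maps,
    feature_mins = mins,
    feature_maxs = maxs
  ), class = "preprocessor_state")
}

#' Apply fitted preprocessing to a raw table
#'
#' Imputation -> encoding -> min-max scaling, using only the fitted
#' statistics. Values outside the fitted range are clipped to [0, 1];
#' constant columns map to 0; unseen categorical levels are mapped to a
#' reserved code equal to the fitted map size (then scaled and clipped).
#'
#' @param state A `preprocessor_state` from [fit_preprocessor()].
#' @param table A raw table containing at least the fitted feature columns.
#' @return Numeric matrix (subjects x features) in [0, 1], feature columns in
#'   the fitted order, rownames set to subject ids when an id column is
#'   present.
#' @export
apply_preprocessor <- function(state, table) {
  stopifnot(inherits(state, "preprocessor_state"))
  absent <- setdiff(state$feature_order, names(table))
  if (length(absent)) stop("table lacks fitted columns: ", paste(absent, collapse = ", "))
  n <- nrow(table)
  out <- matrix(0, n, length(state$feature_order),
                dimnames = list(NULL, state$feature_order))
  for (col in state$feature_order) {
    x <- table[[col]]
    if (col %in% names(state$category_maps)) {
      map <- state$category_maps[[col]]
      x <- as.character(x)
      x[!is.na(x) & x == ""] <- NA_character_
      x[is.na(x)] <- state$medians[[col]]
      codes <- map[x]
      codes[is.na(codes)] <- length(map)  # reserved code for unseen levels
      x <- unname(codes)
    } else {
      x <- as.numeric(x)
      x[is.na(x)] <- state$medians[[col]]
    }
    lo <- state$feature_mins[col]; hi <- state$feature_maxs[col]
    s <- if (hi > lo) (x - lo) / (hi - lo) else rep(0, n)
    out[, col] <- pmin(pmax(s, 0), 1)
  }
  idc <- state$id_columns[state$id_columns %in% names(table)]
  if (length(idc)) rownames(out) <- as.character(table[[idc[1L]]])
  out
}

#' Encode diagnosis labels
#'
#' Maps the diagnosis coding 1 = Control, 2 = ASD to the internal 0/1 coding
#' (positive class ASD = 1).
#'
#' @param dx Vector with values in `{1, 2}`.
#' @return Integer 0/1 vector with a `onehot` attribute (n x 2 matrix,
#'   columns Control, ASD).
#' @export
encode_labels <- function(dx) {
  dx <- as.integer(dx)
  if (any(is.na(dx)) || !all(dx %in% c(1L, 2L)))
    stop("diagnosis values must all be 1 (Control) or 2 (ASD)")
  y <- dx - 1L
  onehot <- cbind(Control = 1L - y, ASD = y)
  attr(y, "onehot") <- onehot
  y
}

#' One-hot view of a 0/1 label vector
#' @param y 0/1 labels.
#' @return n x 2 matrix with one 1 per row.
#' @export
label_onehot <- function(y) {
  y <- as.integer(y)
  stopifnot(all(y %in% 0:1))
  cbind(Control = 1L - y, ASD = y)
}

#' Align behavioral and MRI modalities by subject id
#'
#' Retains only subjects present in both modalities, index-aligned in sorted
#' id order.
#'
#' @param behavioral Feature matrix with subject-id rownames.
#' @param mri_ids Character vector of subject ids with MRI data.
#' @param labels 0/1 labels named by subject id.
#' @return List with `behavioral`, `ids`, `labels`, all aligned.
#' @export
align_modalities <- function(behavioral, mri_ids, labels) {
  bids <- rownames(behavioral)
  if (is.null(bids)) stop("behavioral matrix has no subject-id rownames")
  ids <- sort(intersect(bids, mri_ids))
  if (!length(ids)) stop("no subjects present in both modalities")
  list(behavioral = behavioral[ids, , drop = FALSE],
       ids = ids,
       labels = labels[ids])
}

#' Serialize preprocessing state to JSON
#' @param state A `preprocessor_state`.
#' @param path Output path.
#' @export
write_preprocessor <- function(state, path) {
  s <- unclass(state)
  s$category_maps <- lapply(s$category_maps, as.list)  # keep level names in JSON
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read preprocessing state from JSON
#' @param path Path written by [write_preprocessor()].
#' @return A `preprocessor_state`.
#' @export
read_preprocessor <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- unlist(s$feature_order)
  structure(list(
    id_columns = unlist(s$id_columns),
    label_column = unlist(s$label_column),
    feature_order = feats,
    medians = lapply(s$medians, function(m) m[[1]] %||% m),
    category_maps = lapply(s$category_maps, function(m)
      stats::setNames(as.integer(unlist(m)), names(m))),
    feature_mins = stats::setNames(as.numeric(unlist(s$feature_mins)), feats),
    feature_maxs = stats::setNames(as.numeric(unlist(s$feature_maxs)), feats)
  ), class = "preprocessor_state")
}
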