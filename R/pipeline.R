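# Full-pipeline orchestration: preprocess -> behavioral network -> MRI
# encoder -> autoencoder fusion -> hypernetwork classifier, with every stage
# fitted on training data only, plus the five-variant ablation harness under
# shared stratified folds.

#' Pipeline configuration
#'
#' Stage configurations default to the standard training schedule (30
#' epochs, Adam, learning rate 1e-3); per-stage seeds are derived from the
#' master seed so a single integer reproduces the whole run.
#'
#' @param test_fraction Held-out fraction for [run_pipeline()] (default 0.2,
#'   stratified).
#' @param seed Master integer seed.
#' @param gami A [gami_config()], or `NULL` for defaults.
#' @param mri An [encoder_config()], or `NULL` for defaults.
#' @param ae_bottleneck,ae_hidden Autoencoder widths.
#' @param behavioral_vector If `TRUE`, append the per-feature effect
#'   contributions to the behavioral scalar in the fusion input.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(test_fraction = 0.2, seed = 42L,
                            gami = NULL, mri = NULL,
                            ae_bottleneck = 32L, ae_hidden = 64L,
                            behavioral_vector = FALSE) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  structure(list(test_fraction = test_fraction, seed = as.integer(seed),
                 gami = gami, mri = mri,
                 ae_bottleneck = as.integer(ae_bottleneck),
                 ae_hidden = as.integer(ae_hidden),
                 behavioral_vector = isTRUE(behavioral_vector)),
            class = "pipeline_config")
}

.resolve_stage_configs <- function(config) {
  if (is.null(config$gami)) config$gami <- gami_config(seed = derive_seed(config$seed, 11L))
  if (is.null(config$mri)) config$mri <- encoder_config(seed = derive_seed(config$seed, 12L))
  config
}

# Stratified holdout: returns list(train, test) index vectors.
.stratified_split <- function(y, test_fraction, seed) {
  with_seed(seed, {
    test <- integer(0)
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      n_test <- max(1L, round(length(idx) * test_fraction))
      test <- c(test, idx[seq_len(n_test)])
    }
    sort(test)
  })
}

# Fit the two modality encoders on the training subjects and return
# embeddings for everyone. Shared by run_pipeline and run_ablation.
.fit_modalities <- function(cohort, train, config) {
  pre <- fit_preprocessor(cohort$behavioral[train, , drop = FALSE])
  X_train <- apply_preprocessor(pre, cohort$behavioral[train, , drop = FALSE])
  X_all <- apply_preprocessor(pre, cohort$behavioral)
  y <- unname(cohort$labels)

  gami <- fit_gami(X_train, y[train], config$gami)
  prob_all <- gami_predict(gami, X_all)

  mri <- fit_mri_encoder(cohort$volumes[train], cohort$atlas, y[train], config$mri)
  emb_all <- mri_embed(mri, cohort$volumes)

  behavioral_block <- if (config$behavioral_vector)
    cbind(asd_prob = unname(prob_all), gami_effects(gami, X_all))
  else unname(prob_all)

  list(preprocessor = pre, gami = gami, mri = mri,
       X_all = X_all, prob_all = prob_all, emb_all = emb_all,
       behavioral_block = behavioral_block, y = y)
}

#' Run the full multimodal pipeline on a cohort
#'
#' Stratified train/test split; preprocessing statistics, both modality
#' encoders, the fusion autoencoder and the hypernetwork classifier are all
#' fitted on the training split only; metrics are reported on the held-out
#' split.
#'
#' @param cohort A `synthetic_cohort` (or compatible list with `behavioral`,
#'   `volumes`, `atlas`, `labels`).
#' @param config A [pipeline_config()].
#' @return An `asdfuse_pipeline` with `metrics` (held-out
#'   [metrics_from_confusion()] report incl. AUC), `roc`, `predictions`,
#'   `split`, and the fitted stage models.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  config <- .resolve_stage_configs(config)
  y <- unname(cohort$labels)
  n <- length(y)
  test <- .stratified_split(y, config$test_fraction, derive_seed(config$seed, 1L))
  train <- setdiff(seq_len(n), test)

  stage <- tryCatch(.fit_modalities(cohort, train, config),
                    error = function(e) stop("modality stage failed: ",
                                             conditionMessage(e), call. = FALSE))

  fusion_in <- concat_embeddings(stage$behavioral_block, stage$emb_all)
  ae <- fit_autoencoder(fusion_in[train, , drop = FALSE],
                        bottleneck = config$ae_bottleneck,
                        hidden = config$ae_hidden,
                        seed = derive_seed(config$seed, 13L))
  Z_all <- ae_encode(ae, fusion_in)

  hyper <- train_hypernet(Z_all[train, , drop = FALSE], y[train],
                          seed = derive_seed(config$seed, 14L))
  pred <- hypernet_predict(hyper, Z_all[test, , drop = FALSE])

  roc <- roc_auc(y[test], pred$probs[, "p_asd"])
  metrics <- metrics_from_confusion(confusion(y[test], pred$labels), auc = roc$auc)

  ids <- names(cohort$labels) %||% as.character(seq_len(n))
  structure(list(
    metrics = metrics,
    roc = roc,
    predictions = data.frame(subject_id = ids[test],
                             y_true = y[test],
                             p_control = pred$probs[, 1L],
                             p_asd = pred$probs[, 2L],
                             label = pred$labels,
                             row.names = NULL),
    split = list(train = train, test = test),
    models = list(preprocessor = stage$preprocessor, gami = stage$gami,
                  mri = stage$mri, autoencoder = ae, hypernet = hyper),
    latent = Z_all,
    config = config
  ), class = "asdfuse_pipeline")
}

#' @export
print.asdfuse_pipeline <- function(x, ...) {
  cat("Multimodal pipeline - held-out performance",
      sprintf("(n_test = %d)\n", nrow(x$predictions)))
  print(x$metrics)
  invisible(x)
}

.ablation_variant_names <- c("full", "no_autoencoder", "no_gami",
                             "no_cnn_gnn", "no_hypernetwork")

#' Five-variant ablation under shared stratified cross-validation
#'
#' Evaluates the full pipeline and four reduced variants under the same
#' k-fold partition and per-stage seeds: removing the fusion autoencoder
#' (raw standardized concatenation to the classifier), removing the
#' behavioral branch (MRI embedding only), removing the MRI branch
#' (behavioral probability only), and replacing the hypernetwork with a
#' fixed-weight MLP of matching geometry. The modality encoders are fitted
#' once per fold and shared by every variant, so variants differ only in the
#' stage under ablation.
#'
#' @param cohort A `synthetic_cohort`.
#' @param config A [pipeline_config()].
#' @param k Number of folds (default 5).
#' @return An `ablation_report`: named list of five elements, each with
#'   pooled cross-validated `metrics` and per-fold accuracies.
#' @export
run_ablation <- function(cohort, config = pipeline_config(), k = 5L) {
  config <- .resolve_stage_configs(config)
  y <- unname(cohort$labels)
  n <- length(y)
  folds <- stratified_kfold(y, k, seed = derive_seed(config$seed, 2L))

  pred_pool <- lapply(.ablation_variant_names, function(v)
    list(y = integer(0), lab = integer(0), score = numeric(0), fold_acc = numeric(0)))
  names(pred_pool) <- .ablation_variant_names

  for (f in seq_len(k)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    stage <- .fit_modalities(cohort, train, config)
    seed_f <- derive_seed(config$seed, 100L + f)

    classify <- function(Z_all) {
      m <- train_hypernet(Z_all[train, , drop = FALSE], y[train], seed = seed_f)
      hypernet_predict(m, Z_all[test, , drop = FALSE])
    }
    fuse <- function(inputs) {
      ae <- fit_autoencoder(inputs[train, , drop = FALSE],
                            bottleneck = config$ae_bottleneck,
                            hidden = config$ae_hidden, seed = seed_f)
      ae_encode(ae, inputs)
    }

    concat_full <- concat_embeddings(stage$behavioral_block, stage$emb_all)
    variants <- list(
      full = classify(fuse(concat_full)),
      no_autoencoder = {
        mu <- colMeans(concat_full[train, , drop = FALSE])
        sg <- apply(concat_full[train, , drop = FALSE], 2L, sd)
        sg[sg < 1e-12] <- 1
        classify(sweep(sweep(concat_full, 2L, mu), 2L, sg, "/"))
      },
      no_gami = classify(fuse(stage$emb_all)),
      no_cnn_gnn = classify(fuse(as.matrix(stage$behavioral_block))),
      no_hypernetwork = {
        Z <- fuse(concat_full)
        m <- fit_fixed_mlp(Z[train, , drop = FALSE], y[train],
                           hidden = 16L, seed = seed_f)
        predict(m, Z[test, , drop = FALSE])
      }
    )
    for (v in .ablation_variant_names) {
      pr <- variants[[v]]
      pred_pool[[v]]$y <- c(pred_pool[[v]]$y, y[test])
      pred_pool[[v]]$lab <- c(pred_pool[[v]]$lab, pr$labels)
      pred_pool[[v]]$score <- c(pred_pool[[v]]$score, pr$probs[, 2L])
      pred_pool[[v]]$fold_acc <- c(pred_pool[[v]]$fold_acc,
                                   mean(pr$labels == y[test]))
    }
  }

  report <- lapply(pred_pool, function(pp) {
    roc <- roc_auc(pp$y, pp$score)
    list(metrics = metrics_from_confusion(confusion(pp$y, pp$lab), auc = roc$auc),
         fold_accuracy = pp$fold_acc)
  })
  structure(report, class = "ablation_report", k = k)
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("Ablation study (", attr(x, "k"), "-fold stratified CV)\n", sep = "")
  for (v in names(x)) {
    m <- x[[v]]$metrics
    cat(sprintf("  %-16s accuracy %.3f  auc %s  f1 %s\n", v,
                m$accuracy, format(m$auc, digits = 3), format(m$f1, digits = 3)))
  }
  invisible(x)
}
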