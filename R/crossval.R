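## End-to-end stratified cross-validation of the seating classifier on a
## set of condyle/fossa label volumes.
##
## Per fold: training joints (plus their mirrored copies when enabled) are
## re-cast every epoch under freshly sampled rigid perturbations with
## stochastic (uniform) imputation; validation features are extracted once,
## deterministically (zero perturbation, midpoint imputation).  Mirrored
## copies are created from training joints only, so they can never leak
## into a validation fold.

#' Run stratified k-fold cross-validation on labeled volumes
#'
#' @param volumes named list of [label_volume]s (names = joint ids).
#' @param labels named label vector aligned by joint id
#'   (`"correct"`/`"incorrect"`).
#' @param ds a `direction_set` (default 198 directions).
#' @param spec a [network_spec]; its `input_dim` must equal `ds$n`.
#' @param train_cfg a [training_config].
#' @param aug_cfg an [augmentation_config].
#' @param pred_cfg a [prediction_config].
#' @param k number of folds, default 5.
#' @param rng_seed master seed; the fold split, weight init, shuffling,
#'   perturbations and imputation draws all derive named streams from it.
#' @return A `crossval_result`: per-fold metrics/AUC/confusion, pooled
#'   confusion and metrics, pooled AUC, mean AUC over folds, per-joint
#'   validation confidences, and the fold assignments.
#' @export
run_crossval <- function(volumes, labels,
                         ds = build_direction_set(),
                         spec = network_spec(input_dim = ds$n),
                         train_cfg = training_config(),
                         aug_cfg = augmentation_config(),
                         pred_cfg = prediction_config(),
                         k = 5L, rng_seed = 0L) {
  ids <- names(volumes)
  if (is.null(ids) || is.null(names(labels)))
    stop("'volumes' and 'labels' must be named by joint id")
  labels <- labels[ids]
  if (anyNA(labels)) stop("labels missing for some joints")
  if (spec$input_dim != ds$n)
    stop("network input_dim (", spec$input_dim,
         ") must equal the direction count (", ds$n, ")")
  folds <- stratified_kfold(labels, k = k,
                            rng_seed = derive_seed(rng_seed, "split"))
  centroids <- lapply(volumes, condyle_centroid)
  fold_results <- vector("list", k)
  all_conf <- numeric(0); all_true <- character(0)
  all_pred <- character(0); all_id <- character(0); all_fold <- integer(0)
  for (f in seq_len(k)) {
    val_ids <- ids[folds$assignments == f]
    train_ids <- ids[folds$assignments != f]
    # static mirror doubling of the training joints
    tr_vols <- volumes[train_ids]
    tr_cent <- centroids[train_ids]
    tr_labs <- labels[train_ids]
    if (aug_cfg$mirror) {
      mir <- lapply(volumes[train_ids], mirror_pair)
      names(mir) <- paste0(train_ids, "_mirror")
      tr_vols <- c(tr_vols, mir)
      tr_cent <- c(tr_cent, lapply(mir, condyle_centroid))
      tr_labs <- c(tr_labs, stats::setNames(labels[train_ids], names(mir)))
    }
    tr_ids <- names(tr_vols)
    fold_aug <- augmentation_config(aug_cfg$max_translation_mm,
                                    aug_cfg$max_rotation_deg,
                                    mirror = aug_cfg$mirror,
                                    rng_seed = derive_seed(rng_seed, "aug", f))
    provider <- function(epoch) {
      t(vapply(seq_along(tr_ids), function(j) {
        id <- tr_ids[j]
        p <- sample_perturbation(fold_aug, epoch, id)
        extract_features(tr_vols[[j]], ds, perturbation = p,
                         imputation = "uniform",
                         rng_seed = derive_seed(fold_aug$rng_seed,
                                                "impute", epoch, id),
                         joint_id = id, centroid = tr_cent[[j]])$distances
      }, numeric(ds$n)))
    }
    fold_cfg <- train_cfg
    fold_cfg$rng_seed <- derive_seed(rng_seed, "train", f)
    model <- train_classifier(NULL, tr_labs, spec = spec, cfg = fold_cfg,
                              feature_provider = provider)
    val_feat <- t(vapply(val_ids, function(id)
      extract_features(volumes[[id]], ds, perturbation = NULL,
                       imputation = "midpoint", joint_id = id,
                       centroid = centroids[[id]])$distances,
      numeric(ds$n)))
    pred <- predict_seating(model, val_feat, pred_cfg)
    cm <- confusion(labels[val_ids], pred$label)
    auc <- roc_auc(pred$confidence, labels[val_ids])
    fold_results[[f]] <- list(fold = f, n_val = length(val_ids),
                              confusion = cm,
                              metrics = compute_metrics(cm), auc = auc,
                              loss_trace = model$loss_trace)
    all_conf <- c(all_conf, pred$confidence)
    all_true <- c(all_true, unname(labels[val_ids]))
    all_pred <- c(all_pred, pred$label)
    all_id <- c(all_id, val_ids)
    all_fold <- c(all_fold, rep(f, length(val_ids)))
  }
  pooled_cm <- pool_confusion(lapply(fold_results, `[[`, "confusion"))
  structure(list(
    folds = fold_results,
    pooled_confusion = pooled_cm,
    pooled_metrics = compute_metrics(pooled_cm),
    pooled_auc = roc_auc(all_conf, all_true),
    mean_fold_auc = mean(vapply(fold_results, `[[`, numeric(1), "auc")),
    predictions = data.frame(joint_id = all_id, fold = all_fold,
                             true_label = all_true,
                             confidence = all_conf, pred_label = all_pred,
                             stringsAsFactors = FALSE),
    assignments = folds$assignments,
    k = k, rng_seed = rng_seed),
    class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  m <- x$pooled_metrics
  cat(sprintf("crossval_result: %d folds, %d joints\n",
              x$k, nrow(x$predictions)))
  cat(sprintf("  pooled accuracy %.2f, sensitivity %.2f, specificity %.2f\n",
              m$accuracy, m$sensitivity, m$specificity))
  cat(sprintf("  pooled AUC %.3f, mean fold AUC %.3f\n",
              x$pooled_auc, x$mean_fold_auc))
  invisible(x)
}

#' Serialize a cross-validation result to metrics JSON
#'
#' Per-fold and pooled blocks with the six metrics, AUC and confusion
#' counts.  Deterministic: identical results produce byte-identical files.
#'
#' @param result a `crossval_result`.
#' @param path output JSON path.
#' @export
write_metrics_json <- function(result, path) {
  blk <- function(cm, metrics, auc) list(
    confusion = cm[c("TP", "FP", "TN", "FN")],
    metrics = metrics, auc = auc)
  out <- list(
    k = result$k,
    rng_seed = result$rng_seed,
    folds = lapply(result$folds, function(fr)
      c(list(fold = fr$fold, n_val = fr$n_val),
        blk(fr$confusion, fr$metrics, fr$auc))),
    pooled = blk(result$pooled_confusion, result$pooled_metrics,
                 result$pooled_auc),
    mean_fold_auc = result$mean_fold_auc)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}
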