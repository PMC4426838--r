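# High-level pipeline: stratified k-fold cross-validated MKL with
# out-of-fold decision values, Platt calibration on those out-of-fold
# values, per-fold AUCs and per-group single-kernel baselines.

#' Cross-validated MKL with out-of-fold calibration
#'
#' Runs stratified k-fold cross-validation of the full MKL pipeline:
#' per fold, base kernels are fitted on the training rows only
#' (standardization included), an MKL-SVM is trained, and decision
#' values are computed for the held-out rows. The Platt sigmoid is then
#' fitted on the pooled out-of-fold decision values, so posteriors are
#' never calibrated on examples the SVM memorized.
#'
#' @param dataset a [variant_dataset()] with labels in `{-1, +1}`.
#' @param features the aligned [feature_group_set()]; rows must be
#'   complete in every selected group (see [assemble_training_set()]).
#' @param groups feature groups to use (default all).
#' @param k folds (default 5).
#' @param C SVM regularization constant (default 1).
#' @param kind kernel form, `"linear"` or `"rbf"`.
#' @param seed fold-shuffle seed.
#' @return an `mkl_cv` list: `phi` (out-of-fold decision values, in
#'   dataset order), `fold` (fold id per row), `auc` (per-fold test
#'   AUC), `weights` (per-fold learned kernel weights, folds in rows),
#'   `calibrator` (Platt fit on out-of-fold `phi`), `records`
#'   (out-of-fold [prediction_records()]), `folds` (the index lists).
#' @export
mkl_cv <- function(dataset, features, groups = NULL, k = 5, C = 1,
                   kind = "linear", seed = NULL) {
  if (!is.null(groups)) features <- features_subset(features, groups = groups)
  labels <- dataset$label
  if (!all(labels %in% c(-1L, 1L)))
    stop_("all variants must be labeled -1/+1 for cross-validation")
  folds <- kfold_cv(labels, k = k, stratified = TRUE, seed = seed)
  n <- nrow(dataset)
  phi <- rep(NA_real_, n)
  fold_id <- integer(n)
  auc <- numeric(k)
  W <- matrix(NA_real_, k, length(features$group_names),
              dimnames = list(NULL, features$group_names))
  avail <- matrix(TRUE, n, length(features$group_names),
                  dimnames = list(NULL, features$group_names))
  for (f in seq_len(k)) {
    tr <- folds[[f]]$train
    te <- folds[[f]]$test
    ktrain <- compute_base_kernels(features_subset(features, tr), kind = kind)
    model <- train_mkl(ktrain, labels[tr], C = C)
    ck <- cross_kernels(ktrain, features_subset(features, te))
    phi[te] <- decision_function(model, ck)
    avail[te, ] <- ck$available
    fold_id[te] <- f
    auc[f] <- roc_auc(phi[te], labels[te])
    W[f, ] <- model$weights
  }
  cal <- fit_platt(phi[!is.na(phi)], labels[!is.na(phi)])
  records <- prediction_records(variant_keys(dataset), phi, cal,
                                groups_used = avail)
  list(phi = phi, fold = fold_id, auc = auc, weights = W,
       calibrator = cal, records = records, folds = folds)
}

#' Per-group single-kernel cross-validated AUCs
#'
#' Baseline for judging the composite model: each feature group alone,
#' same folds, same SVM.
#'
#' @inheritParams mkl_cv
#' @return named vector of mean out-of-fold AUC per group.
#' @export
single_kernel_aucs <- function(dataset, features, k = 5, C = 1,
                               kind = "linear", seed = NULL) {
  vapply(stats::setNames(nm = features$group_names), function(g) {
    mean(mkl_cv(dataset, features, groups = g, k = k, C = C, kind = kind,
                seed = seed)$auc)
  }, numeric(1))
}

#' Train a deployable model on the full dataset
#'
#' Fits kernels and the MKL-SVM on all rows, and calibrates the Platt
#' sigmoid on out-of-fold decision values from an internal
#' cross-validation ([mkl_cv()]) under the same settings.
#'
#' @inheritParams mkl_cv
#' @param calibration_folds folds for the internal calibration CV.
#' @return list with `model` (an `mkl_model`), `calibrator`, `cv`
#'   (the internal `mkl_cv` result) and `groups`.
#' @export
train_full <- function(dataset, features, groups = NULL, C = 1,
                       kind = "linear", calibration_folds = 5,
                       seed = NULL) {
  if (!is.null(groups)) features <- features_subset(features, groups = groups)
  cv <- mkl_cv(dataset, features, k = calibration_folds, C = C,
               kind = kind, seed = seed)
  kset <- compute_base_kernels(features, kind = kind)
  model <- train_mkl(kset, dataset$label, C = C)
  list(model = model, calibrator = cv$calibrator, cv = cv,
       groups = features$group_names)
}
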