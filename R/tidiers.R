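#' Tidy a trained diagnosis forest
#'
#' @param x An [mw_forest][train_forest()].
#' @param ... Unused.
#' @return A tibble with one row per feature: `term`, `importance`
#'   (raw permutation importance).
#' @method tidy mw_forest
#' @export
tidy.mw_forest <- function(x, ...) {
  tibble::tibble(term = names(x$importance),
                 importance = as.numeric(x$importance))
}

#' One-row summary of a trained diagnosis forest
#'
#' @inheritParams tidy.mw_forest
#' @return A tibble with the configuration, OOB error and data size.
#' @method glance mw_forest
#' @export
glance.mw_forest <- function(x, ...) {
  tibble::tibble(
    n_trees = x$config$n_trees,
    n_features_per_split = x$fit$mtry,
    min_leaf_size = x$config$min_leaf_size,
    oob_error = x$oob_error,
    n_obs = x$n_obs,
    n_features = length(x$feature_names)
  )
}

#' Tidy nested cross-validation results
#'
#' @param x An [mw_cv][nested_cv()].
#' @param ... Unused.
#' @return The per-fold tibble (AUC and chosen configuration per fold).
#' @method tidy mw_cv
#' @export
tidy.mw_cv <- function(x, ...) x$folds

#' One-row summary of nested cross-validation results
#'
#' @inheritParams tidy.mw_cv
#' @return A tibble with the architecture and the fold-averaged AUC.
#' @method glance mw_cv
#' @export
glance.mw_cv <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    angle = x$angle,
    k = x$k,
    mean_auc = x$mean_auc,
    sd_auc = sd(x$folds$auc)
  )
}

#' Tidy a ROC curve
#'
#' @param x A [roc_curve()].
#' @param ... Unused.
#' @return The threshold/fpr/tpr tibble.
#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, fpr = x$fpr, tpr = x$tpr)
}

#' One-row summary of a ROC curve
#'
#' @inheritParams tidy.roc_curve
#' @return A tibble with `auc` and the number of swept thresholds.
#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), n_thresholds = nrow(x))
}
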