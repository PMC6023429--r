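#' Receiver operating characteristic curve
#'
#' Sweeps the decision threshold over the unique scores (plus a sentinel
#' above the maximum) and records the false and true positive rates of
#' calling "malignant" when `score >= threshold`. The area under the curve
#' is computed by trapezoidal integration, which equals the Mann--Whitney
#' rank statistic (ties credited 1/2).
#'
#' @param scores Numeric malignancy scores.
#' @param labels Class labels (`"malignant"` positive, `"benign"` negative).
#' @return A tibble of class `roc_curve` with columns `threshold`
#'   (descending), `fpr`, `tpr`, and an `auc` attribute.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == "malignant"
  if (!any(pos) || all(pos)) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!pos] >= t), numeric(1))
  out <- tibble::tibble(threshold = th, fpr = fpr, tpr = tpr)
  n <- nrow(out)
  attr(out, "auc") <- sum(diff(fpr) * (tpr[-1] + tpr[-n]) / 2)
  class(out) <- c("roc_curve", class(out))
  out
}

#' Area under the ROC curve
#'
#' @param x A `roc_curve`, or a numeric score vector.
#' @param labels Labels, required when `x` is a score vector.
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(x, labels = NULL) {
  if (inherits(x, "roc_curve")) return(attr(x, "auc"))
  attr(roc_curve(x, labels), "auc")
}

#' Optimal decision threshold (Youden's J)
#'
#' The threshold maximising `tpr - fpr` over the ROC sweep; ties resolve to
#' the lower threshold (the more sensitive operating point).
#'
#' @param roc A [roc_curve()].
#' @return One-row tibble with `threshold` and the achieved `youden_j`.
#' @export
optimal_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$tpr - roc$fpr
  best <- max(j)
  ## thresholds are stored descending; the last maximiser is the lowest
  idx <- max(which(j == best))
  tibble::tibble(threshold = roc$threshold[idx], youden_j = best)
}

#' Relative feature-contribution map
#'
#' Out-of-bag permutation importance of every input dimension of a trained
#' forest, clipped at zero and normalised by the maximum so the dominant
#' contribution is 1. In TW mode the dimensions are the 60 signature time
#' samples; in FE mode the 30 extracted features. For an EAC/MA/EA model
#' wrapper the member forests' maps are averaged before normalisation.
#'
#' @param forest An [mw_forest][train_forest()] or [mw_model][build_model()].
#' @param mode `"FE"` or `"TW"` tag recorded on the map.
#' @param normalise `"max"` (default) or `"sum"`.
#' @return A tibble of class `importance_map` with `term`, `contribution`,
#'   `mode`.
#' @export
feature_contribution_map <- function(forest, mode = c("FE", "TW"),
                                     normalise = c("max", "sum")) {
  mode <- match.arg(mode)
  normalise <- match.arg(normalise)
  imp <- if (inherits(forest, "mw_forest")) {
    forest$importance
  } else if (inherits(forest, "mw_model")) {
    rowMeans(vapply(forest$forests, function(f) f$importance,
                    numeric(length(forest$forests[[1]]$importance))))
  } else {
    stop("`forest` must be a trained mw_forest or mw_model", call. = FALSE)
  }
  v <- pmax(imp, 0)
  denom <- if (normalise == "max") max(v) else sum(v)
  if (denom > 0) v <- v / denom
  out <- tibble::tibble(term = names(imp), contribution = as.numeric(v),
                        mode = mode)
  class(out) <- c("importance_map", class(out))
  out
}
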