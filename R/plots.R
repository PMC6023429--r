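#' Plot a ROC curve
#'
#' @param object A [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_path(colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a relative feature-contribution map
#'
#' Bar map of the max-normalised permutation importances, in input order
#' (time samples for TW mode, features #1--#30 for FE mode).
#'
#' @param object An [feature_contribution_map()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot importance_map
#' @export
autoplot.importance_map <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$term <- factor(d$term, levels = d$term)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$contribution)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::labs(x = NULL, y = "Relative contribution",
                  title = sprintf("Feature contribution map (%s mode)", d$mode[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Plot per-fold ROC curves of a nested cross-validation run
#'
#' @param object An [mw_cv][nested_cv()].
#' @param ... Unused.
#' @return A ggplot with one ROC curve per outer fold.
#' @method autoplot mw_cv
#' @export
autoplot.mw_cv <- function(object, ...) {
  per_fold <- dplyr::group_modify(
    dplyr::group_by(object$predictions, .data$fold),
    function(d, g) tidy(roc_curve(d$fused_score, d$true_label))
  )
  ggplot2::ggplot(per_fold, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                         colour = factor(.data$fold))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate", colour = "Fold",
      title = sprintf("%s %g°: mean AUC %.3f", object$kind, object$angle,
                      object$mean_auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot tumour signatures by class
#'
#' Overlays windowed, aligned 60-sample signatures coloured by tumour class;
#' spiculated (malignant) tumours show visibly more distorted, multi-peaked
#' signatures than smooth (benign) ones.
#'
#' @param signatures Output of [prepare_signatures()].
#' @param max_per_class Signatures drawn per class.
#' @return A ggplot.
#' @export
plot_signatures <- function(signatures, max_per_class = 12) {
  d <- dplyr::slice_head(dplyr::group_by(signatures, .data$label),
                         n = max_per_class)
  d <- dplyr::ungroup(d)
  long <- tidyr::unnest_longer(
    dplyr::mutate(d, row = dplyr::row_number(),
                  sample = lapply(.data$signature, seq_along)),
    c("signature", "sample")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$signature,
                                     group = .data$row, colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "Signature sample (30 GHz)", y = "Amplitude",
                  colour = "Class") +
    ggplot2::theme_minimal()
}
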