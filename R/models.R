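#' Stratified scan-level fold assignment
#'
#' Partitions scans into `k` folds stratified by class: within each class,
#' scans are shuffled (seeded) and dealt round-robin, so per-fold class
#' counts differ from perfect stratification by at most one. All signals of
#' a scan inherit its fold, which keeps whole scans together when splitting
#' into training and test.
#'
#' @param scans Data frame with columns `scan_id` and `label` (one row per
#'   scan).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A tibble `scan_id`, `label`, `fold`.
#' @export
make_folds <- function(scans, k = 5, seed = 1) {
  scans <- dplyr::distinct(tibble::as_tibble(scans[, c("scan_id", "label")]))
  counts <- table(scans$label)
  if (any(counts < k)) {
    stop(sprintf("each class needs at least k = %d scans for %d-fold CV", k, k),
         call. = FALSE)
  }
  withr::local_seed(seed)
  out <- dplyr::group_modify(
    dplyr::group_by(scans, .data$label),
    function(d, g) {
      d <- d[sample.int(nrow(d)), , drop = FALSE]
      d$fold <- rep_len(seq_len(k), nrow(d))
      d
    }
  )
  dplyr::arrange(dplyr::ungroup(out), .data$scan_id)[, c("scan_id", "label", "fold")]
}

#' Majority-vote fusion of per-channel predictions (antenna grouping)
#'
#' Converts independent per-channel predictions into one diagnosis per scan:
#' among the `W` channels closest to the tumour (all channels when `W` is
#' `NULL`), the fused malignancy score is the fraction of malignant votes
#' and the fused label is malignant when the score reaches the decision
#' threshold (ties therefore resolve to malignant, favouring sensitivity in
#' a screening context).
#'
#' @param preds Tibble of per-channel predictions with columns `scan_id`,
#'   `path_mm` (proximity metric from [rank_channels_by_proximity()], used
#'   to order channels; ties broken by `tx`, `rx` when present) and `.score`
#'   (malignancy score in `[0, 1]`).
#' @param W Number of closest channels in the vote; `NULL` uses all.
#' @param threshold Decision threshold on the fused score (and on the
#'   per-channel score when casting votes).
#' @return A tibble `scan_id`, `fused_score`, `fused_label`, `w_used`.
#' @export
antenna_grouping <- function(preds, W = NULL, threshold = 0.5) {
  stopifnot(all(c("scan_id", "path_mm", ".score") %in% names(preds)))
  n_ch <- min(table(preds$scan_id))
  if (!is.null(W) && (W < 1 || W > n_ch)) {
    stop(sprintf("W must lie in [1, %d]", n_ch), call. = FALSE)
  }
  sort_cols <- intersect(c("path_mm", "tx", "rx"), names(preds))
  preds <- dplyr::arrange(preds, !!!rlang::syms(c("scan_id", sort_cols)))
  grouped <- dplyr::group_by(preds, .data$scan_id)
  if (!is.null(W)) grouped <- dplyr::slice_head(grouped, n = W)
  out <- dplyr::summarise(
    grouped,
    fused_score = mean(.data$.score >= threshold),
    w_used = dplyr::n(),
    .groups = "drop"
  )
  out$fused_label <- ifelse(out$fused_score >= threshold, "malignant", "benign")
  out[, c("scan_id", "fused_score", "fused_label", "w_used")]
}

## predictor columns of a processed table: t01..t60 (TW) or f01..f30 (FE)
predictor_cols <- function(data) {
  grep("^[tf][0-9]{2}$", names(data), value = TRUE)
}

#' Build an EA, MA or EAC classification model
#'
#' Trains the channel-angle architectures: an equal-angle (EA) model uses
#' only channels at exactly one angle `Z`; a multiple-angle (MA) model pools
#' all channels with angle in `[0, angle]`; an equal-angle-combined (EAC)
#' model holds one EA member per distinct angle in `[0, angle]` and fuses
#' the members' scan-level decisions by unweighted majority vote (each
#' member applies its own antenna grouping first; member ties resolve to
#' malignant).
#'
#' @param data Processed per-channel table (from [signature_table()] or
#'   [extract_feature_table()]): columns `scan_id`, `label`, `angle`,
#'   `path_mm` and the predictor columns `t01..t60` or `f01..f30`.
#' @param kind `"EA"`, `"MA"` or `"EAC"`.
#' @param angle The EA angle, or the upper bound of the MA/EAC range,
#'   degrees.
#' @param config A [forest_config()] shared by all member forests.
#' @param seed Integer seed.
#' @return An object of class `mw_model` with fields `kind`, `angles`,
#'   `forests` (named list), `config`.
#' @export
build_model <- function(data, kind = c("EA", "MA", "EAC"), angle,
                        config = forest_config(), seed = 1) {
  kind <- match.arg(kind)
  pred_cols <- predictor_cols(data)
  stopifnot(length(pred_cols) > 0, all(c("scan_id", "label", "angle") %in% names(data)))
  angles_present <- sort(unique(data$angle))
  model_angles <- switch(kind,
    EA = angle,
    MA = angles_present[angles_present <= angle],
    EAC = angles_present[angles_present <= angle]
  )
  if (kind == "EA" && !angle %in% angles_present) {
    stop(sprintf("no channels at angle %g in the data", angle), call. = FALSE)
  }
  if (length(model_angles) == 0L) {
    stop("no channels in the requested angle range", call. = FALSE)
  }
  forests <- if (kind == "EAC") {
    out <- lapply(seq_along(model_angles), function(i) {
      d <- data[data$angle == model_angles[i], , drop = FALSE]
      train_forest(d[, pred_cols], d$label, config, seed = seed + i - 1L)
    })
    names(out) <- sprintf("EA_%g", model_angles)
    out
  } else {
    d <- if (kind == "EA") {
      data[data$angle == angle, , drop = FALSE]
    } else {
      data[data$angle <= angle, , drop = FALSE]
    }
    list(main = train_forest(d[, pred_cols], d$label, config, seed = seed))
  }
  structure(
    list(kind = kind, angle = angle, angles = model_angles,
         forests = forests, config = config, pred_cols = pred_cols),
    class = "mw_model"
  )
}

#' @export
print.mw_model <- function(x, ...) {
  cat(sprintf("<mw_model> %s, angle(s) %s, %d forest(s), %d predictors\n",
              x$kind, paste(x$angles, collapse = "/"),
              length(x$forests), length(x$pred_cols)))
  invisible(x)
}

#' Scan-level diagnoses from a classification model
#'
#' Scores every channel row the model consumes, then fuses per-channel votes
#' into one diagnosis per scan with the ranked antenna-grouping majority
#' vote. For EAC models each member EA model fuses its own channels first
#' and the members' decisions are combined by unweighted majority (score =
#' mean member fused score; label ties resolve to malignant).
#'
#' @param model An [build_model()] result.
#' @param data Processed per-channel table with the model's predictor
#'   columns, `scan_id`, `angle`, `path_mm`.
#' @param W Number of closest channels in each antenna-grouping vote;
#'   `NULL` uses all available.
#' @param threshold Decision threshold.
#' @return A tibble `scan_id`, `fused_score`, `fused_label`, `w_used`.
#' @export
predict_scans <- function(model, data, W = NULL, threshold = 0.5) {
  stopifnot(inherits(model, "mw_model"))
  if (model$kind == "EAC") {
    member <- lapply(seq_along(model$angles), function(i) {
      d <- data[data$angle == model$angles[i], , drop = FALSE]
      sc <- predict(model$forests[[i]], d[, model$pred_cols])
      g <- antenna_grouping(dplyr::bind_cols(d[, setdiff(names(d), model$pred_cols)], sc),
                            W = W, threshold = threshold)
      g$member <- names(model$forests)[i]
      g
    })
    all_m <- dplyr::bind_rows(member)
    out <- dplyr::summarise(
      dplyr::group_by(all_m, .data$scan_id),
      fused_score = mean(.data$fused_score),
      vote = mean(.data$fused_label == "malignant"),
      w_used = sum(.data$w_used),
      .groups = "drop"
    )
    out$fused_label <- ifelse(out$vote >= 0.5, "malignant", "benign")
    out[, c("scan_id", "fused_score", "fused_label", "w_used")]
  } else {
    d <- if (model$kind == "EA") {
      data[data$angle == model$angle, , drop = FALSE]
    } else {
      data[data$angle <= model$angle, , drop = FALSE]
    }
    sc <- predict(model$forests$main, d[, model$pred_cols])
    antenna_grouping(dplyr::bind_cols(d[, setdiff(names(d), model$pred_cols)], sc),
                     W = W, threshold = threshold)
  }
}

#' Per-channel scores from a classification model
#'
#' The un-fused predictions: one malignancy score per channel row the model
#' consumes. Useful for comparing per-channel accuracy against the
#' antenna-grouped diagnosis.
#'
#' @inheritParams predict_scans
#' @return The consumed rows of `data` (metadata columns) with `.score` and
#'   `.label` appended.
#' @export
predict_channels <- function(model, data, threshold = 0.5) {
  stopifnot(inherits(model, "mw_model"))
  rows <- if (model$kind == "EA") {
    list(data[data$angle == model$angle, , drop = FALSE])
  } else if (model$kind == "MA") {
    list(data[data$angle <= model$angle, , drop = FALSE])
  } else {
    lapply(model$angles, function(a) data[data$angle == a, , drop = FALSE])
  }
  forests <- if (model$kind == "EAC") model$forests else model$forests["main"]
  out <- Map(function(d, f) {
    sc <- predict(f, d[, model$pred_cols], threshold = threshold)
    dplyr::bind_cols(d[, setdiff(names(d), model$pred_cols)], sc)
  }, rows, forests)
  dplyr::bind_rows(out)
}

#' Nested cross-validation of a diagnosis model
#'
#' Outer `k`-fold stratified cross-validation at scan level (all channels of
#' a scan stay on one side of every split; the train/test scan sets are
#' verified disjoint on every fold). Within each outer fold the forest
#' hyperparameters are optionally optimised on the training scans only,
#' using the out-of-bag error as the inner criterion (no inner CV loop is
#' needed); the model is then trained on the training scans and scan-level
#' diagnoses are produced for the test scans. Reported performance is the
#' average AUC over the outer test folds.
#'
#' @param data Processed per-channel table (see [build_model()]).
#' @param kind,angle Model architecture.
#' @param k Number of outer folds.
#' @param config [forest_config()] used when no search is run.
#' @param search_budget If not `NULL`, hyperparameters are optimised per
#'   fold with this evaluation budget (see [optimise_hyperparameters()]);
#'   for EAC models the search runs once per fold on the pooled member rows
#'   and the resulting configuration is shared by all members.
#' @param W,threshold Antenna-grouping parameters.
#' @param seed Integer seed controlling folds, searches and fits.
#' @return An object of class `mw_cv`: list with `folds` (per-fold tibble of
#'   AUC and configuration), `predictions` (scan-level test predictions
#'   across folds), `channel_predictions`, `mean_auc`, `kind`, `angle`, `k`.
#' @export
nested_cv <- function(data, kind = c("EA", "MA", "EAC"), angle, k = 5,
                      config = forest_config(), search_budget = NULL,
                      W = NULL, threshold = 0.5, seed = 1) {
  kind <- match.arg(kind)
  pred_cols <- predictor_cols(data)
  used <- if (kind == "EA") data$angle == angle else data$angle <= angle
  data <- data[used, , drop = FALSE]
  folds <- make_folds(data, k = k, seed = seed)
  data <- dplyr::left_join(data, folds[, c("scan_id", "fold")], by = "scan_id")

  fold_rows <- list()
  pred_rows <- list()
  chan_rows <- list()
  for (f in seq_len(k)) {
    train <- data[data$fold != f, , drop = FALSE]
    test <- data[data$fold == f, , drop = FALSE]
    if (length(intersect(train$scan_id, test$scan_id)) != 0L) {
      stop("internal error: scan-level leakage between train and test", call. = FALSE)
    }
    cfg <- if (!is.null(search_budget)) {
      optimise_hyperparameters(train[, pred_cols], train$label,
                               budget = search_budget, seed = seed + 100 * f)
    } else {
      config
    }
    model <- build_model(train, kind, angle, cfg, seed = seed + 1000 * f)
    preds <- predict_scans(model, test, W = W, threshold = threshold)
    truth <- dplyr::distinct(test[, c("scan_id", "label")])
    preds <- dplyr::left_join(preds, truth, by = "scan_id")
    names(preds)[names(preds) == "label"] <- "true_label"
    preds$fold <- f
    pred_rows[[f]] <- preds
    chan <- predict_channels(model, test, threshold = threshold)
    chan$fold <- f
    chan_rows[[f]] <- chan
    fold_rows[[f]] <- tibble::tibble(
      fold = f,
      n_test_scans = nrow(preds),
      auc = roc_auc(preds$fused_score, preds$true_label),
      n_trees = cfg$n_trees,
      n_features_per_split = cfg$n_features_per_split %||% NA_integer_,
      min_leaf_size = cfg$min_leaf_size
    )
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  structure(
    list(folds = folds_tbl,
         predictions = dplyr::bind_rows(pred_rows),
         channel_predictions = dplyr::bind_rows(chan_rows),
         mean_auc = mean(folds_tbl$auc),
         kind = kind, angle = angle, k = k, seed = seed),
    class = "mw_cv"
  )
}

#' @export
print.mw_cv <- function(x, ...) {
  cat(sprintf("<mw_cv> %s %g°, %d-fold nested CV: mean AUC %.3f (folds %s)\n",
              x$kind, x$angle, x$k, x$mean_auc,
              paste(sprintf("%.2f", x$folds$auc), collapse = ", ")))
  invisible(x)
}
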