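#' Random-forest hyperparameter configuration
#'
#' The three tuned hyperparameters of the diagnosis forests: number of
#' trees, number of candidate features per split (mtry) and minimum leaf
#' size.
#'
#' @param n_trees Number of trees (>= 1).
#' @param n_features_per_split Features tried at each split; defaults to
#'   `floor(sqrt(p))` at fit time when `NULL`.
#' @param min_leaf_size Minimum terminal-node size (>= 1).
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 100L, n_features_per_split = NULL,
                          min_leaf_size = 1L) {
  stopifnot(n_trees >= 1, min_leaf_size >= 1,
            is.null(n_features_per_split) || n_features_per_split >= 1)
  structure(
    list(n_trees = as.integer(n_trees),
         n_features_per_split = if (is.null(n_features_per_split)) NULL
                                else as.integer(n_features_per_split),
         min_leaf_size = as.integer(min_leaf_size)),
    class = "forest_config"
  )
}

#' @export
print.forest_config <- function(x, ...) {
  cat(sprintf("<forest_config> %d trees, mtry %s, min leaf %d\n",
              x$n_trees,
              if (is.null(x$n_features_per_split)) "sqrt(p)"
              else x$n_features_per_split,
              x$min_leaf_size))
  invisible(x)
}

class_levels <- c("benign", "malignant")

#' Train a random-forest classifier
#'
#' Fits a probability forest on per-channel observations: each tree is grown
#' on a bootstrap sample (leaving about one third of the observations
#' out-of-bag) with random feature subsets at each split. The out-of-bag
#' misclassification error and per-feature permutation importances are
#' recorded.
#'
#' @param features Data frame or matrix of predictors (one row per signal).
#' @param labels Vector of `"benign"` / `"malignant"` class labels.
#' @param config A [forest_config()].
#' @param seed Integer seed; the fit is deterministic under it.
#' @return An object of class `mw_forest` with fields `fit` (the underlying
#'   ensemble), `config`, `oob_error`, `importance`, `feature_names`,
#'   `classes`.
#' @export
train_forest <- function(features, labels, config = forest_config(), seed = 1) {
  stopifnot(inherits(config, "forest_config"))
  features <- as.data.frame(features)
  y <- factor(as.character(labels), levels = class_levels)
  if (anyNA(y)) stop("labels must be 'benign' or 'malignant'", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  if (any(table(y) < 2L)) {
    stop("need at least 2 observations per class", call. = FALSE)
  }
  p <- ncol(features)
  mtry <- min(p, config$n_features_per_split %||% max(1L, floor(sqrt(p))))
  fit <- ranger::ranger(
    x = features, y = y,
    num.trees = config$n_trees,
    mtry = mtry,
    min.node.size = config$min_leaf_size,
    probability = TRUE,
    importance = "permutation",
    seed = seed,
    num.threads = 1
  )
  oob_prob <- fit$predictions[, "malignant"]
  oob_pred <- ifelse(oob_prob >= 0.5, "malignant", "benign")
  oob_error <- mean(oob_pred != as.character(y), na.rm = TRUE)
  structure(
    list(fit = fit, config = config, oob_error = oob_error,
         importance = fit$variable.importance,
         feature_names = colnames(features),
         classes = class_levels, n_obs = nrow(features), seed = seed),
    class = "mw_forest"
  )
}

#' @export
print.mw_forest <- function(x, ...) {
  cat(sprintf("<mw_forest> %d trees on %d obs x %d features, OOB error %.3f\n",
              x$config$n_trees, x$n_obs, length(x$feature_names), x$oob_error))
  invisible(x)
}

#' Predict per-channel malignancy scores
#'
#' @param object An [mw_forest()][train_forest()].
#' @param newdata Data frame with the training feature columns.
#' @param threshold Decision threshold on the malignancy score.
#' @param ... Unused.
#' @return A tibble with `.score` (probability of malignant, the fraction of
#'   tree votes) and `.label`.
#' @export
predict.mw_forest <- function(object, newdata, threshold = 0.5, ...) {
  newdata <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  pr <- predict(object$fit, data = newdata, num.threads = 1)$predictions
  score <- pr[, "malignant"]
  tibble::tibble(
    .score = as.numeric(score),
    .label = ifelse(score >= threshold, "malignant", "benign")
  )
}

default_search_space <- function(p = 30L) {
  list(n_trees = c(50L, 500L),
       n_features_per_split = c(1L, as.integer(p)),
       min_leaf_size = c(1L, 20L))
}

#' Optimise forest hyperparameters on the out-of-bag error
#'
#' Sequential model-based search over `{n_trees, n_features_per_split,
#' min_leaf_size}` minimising the out-of-bag misclassification error: a
#' maximin Latin-hypercube initial design covers the space, then a
#' random-forest surrogate fitted to the evaluated configurations proposes
#' each next candidate by minimum predicted error. Returns the
#' best-evaluated configuration; ties are broken towards fewer trees.
#'
#' @param features,labels Training data as in [train_forest()].
#' @param search_space Named list of integer ranges (length-2 vectors) for
#'   the three hyperparameters.
#' @param budget Total number of configurations to evaluate (>= 5).
#' @param seed Integer seed; the search is deterministic under it.
#' @return A [forest_config()] with an attached `history` attribute (a
#'   tibble of every evaluated configuration and its OOB error).
#' @export
optimise_hyperparameters <- function(features, labels,
                                     search_space = NULL,
                                     budget = 30, seed = 1) {
  if (budget < 5) stop("budget must be at least 5 evaluations", call. = FALSE)
  features <- as.data.frame(features)
  p <- ncol(features)
  if (is.null(search_space)) search_space <- default_search_space(p)
  if (length(search_space) == 0L) stop("empty search space", call. = FALSE)
  stopifnot(all(c("n_trees", "n_features_per_split", "min_leaf_size")
                %in% names(search_space)))
  search_space$n_features_per_split <-
    pmin(search_space$n_features_per_split, p)
  lo <- vapply(search_space, function(r) min(r), numeric(1))
  hi <- vapply(search_space, function(r) max(r), numeric(1))

  withr::local_seed(seed)
  y <- factor(as.character(labels), levels = class_levels)

  eval_oob <- function(cfg) {
    fit <- ranger::ranger(
      x = features, y = y,
      num.trees = cfg[1], mtry = cfg[2], min.node.size = cfg[3],
      probability = FALSE, seed = sample.int(1e6, 1), num.threads = 1
    )
    fit$prediction.error
  }
  unit_to_cfg <- function(u) {
    pmin(hi, lo + floor(u * (hi - lo + 1)))
  }
  rand_cfg <- function(m) {
    t(vapply(seq_len(m), function(i) {
      unit_to_cfg(runif(3))
    }, numeric(3)))
  }

  n_init <- max(5L, min(budget, ceiling(budget / 2)))
  X <- t(apply(lhs::maximinLHS(n_init, 3), 1, unit_to_cfg))
  X <- unique(X)
  while (nrow(X) < n_init) X <- unique(rbind(X, rand_cfg(1L)))
  errs <- apply(X, 1, eval_oob)

  while (nrow(X) < budget) {
    sur <- ranger::ranger(
      x = as.data.frame(X), y = errs, num.trees = 200,
      seed = sample.int(1e6, 1), num.threads = 1
    )
    cand <- rand_cfg(256L)
    cand <- cand[!duplicated(rbind(X, cand))[-seq_len(nrow(X))], , drop = FALSE]
    if (nrow(cand) == 0L) cand <- rand_cfg(1L)
    pred <- predict(sur, data = as.data.frame(cand),
                    num.threads = 1)$predictions
    nxt <- cand[which.min(pred), ]
    X <- rbind(X, nxt)
    errs <- c(errs, eval_oob(nxt))
  }

  ord <- order(errs, X[, 1])
  best <- X[ord[1], ]
  out <- forest_config(best[1], best[2], best[3])
  attr(out, "history") <- tibble::tibble(
    n_trees = X[, 1], n_features_per_split = X[, 2],
    min_leaf_size = X[, 3], oob_error = errs
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
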