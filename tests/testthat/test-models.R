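# small processed feature table built from synthetic separable data:
# per-channel rows with scan/channel metadata and f-column predictors
toy_feature_table <- function(n_scans = 20, n_channels = 6, p = 5, sep = 2,
                              seed = 1) {
  withr::with_seed(seed, {
    scans <- tibble::tibble(
      scan_id = sprintf("s%03d", seq_len(n_scans)),
      label = rep(c("benign", "malignant"), length.out = n_scans)
    )
    rows <- do.call(rbind, lapply(seq_len(n_scans), function(i) {
      mu <- if (scans$label[i] == "malignant") sep else 0
      m <- matrix(rnorm(n_channels * p, mu), n_channels, p)
      colnames(m) <- sprintf("f%02d", seq_len(p))
      cbind(
        data.frame(scan_id = scans$scan_id[i], label = scans$label[i],
                   tx = seq_len(n_channels) - 1L, rx = seq_len(n_channels) - 1L,
                   angle = rep(c(0, 30, 60), length.out = n_channels),
                   path_mm = runif(n_channels, 50, 250)),
        as.data.frame(m)
      )
    }))
    tibble::as_tibble(rows)
  })
}

test_that("fold assignment is a stratified scan-level partition", {
  scans <- tibble::tibble(scan_id = sprintf("s%02d", 1:10),
                          label = rep(c("benign", "malignant"), 5))
  folds <- make_folds(scans, k = 5, seed = 2)
  expect_setequal(folds$scan_id, scans$scan_id)
  expect_equal(unname(table(folds$fold)), rep(2L, 5), ignore_attr = TRUE)
  ## each fold holds one scan of each class
  tab <- table(folds$fold, folds$label)
  expect_true(all(tab == 1))

  expect_error(make_folds(scans[1:6, ], k = 5), "at least k")

  ## larger unbalanced-ish case: per-fold class counts within 1 of perfect
  scans2 <- tibble::tibble(scan_id = sprintf("t%03d", 1:47),
                           label = rep(c("benign", "malignant"), length.out = 47))
  f2 <- make_folds(scans2, k = 5, seed = 3)
  tab2 <- table(f2$fold, f2$label)
  for (cl in colnames(tab2)) {
    expect_lte(max(tab2[, cl]) - min(tab2[, cl]), 1)
  }
})

test_that("antenna grouping is a majority vote over the W closest channels", {
  preds <- tibble::tibble(
    scan_id = "s1",
    path_mm = c(10, 20, 30),
    .score = c(1, 1, 0)    # votes M, M, B in proximity order
  )
  g <- antenna_grouping(preds, W = 3)
  expect_equal(g$fused_label, "malignant")
  expect_equal(g$fused_score, 2 / 3)
  g1 <- antenna_grouping(preds, W = 1)
  expect_equal(g1$fused_label, "malignant")
  expect_equal(g1$w_used, 1)

  expect_error(antenna_grouping(preds, W = 4), "W must lie")
  expect_error(antenna_grouping(preds, W = 0), "W must lie")

  ## tie resolves to malignant
  tie <- tibble::tibble(scan_id = "s1", path_mm = 1:2, .score = c(1, 0))
  expect_equal(antenna_grouping(tie)$fused_label, "malignant")

  ## every W matches a direct count oracle
  withr::with_seed(13, {
    n <- 78
    rp <- tibble::tibble(scan_id = "x", path_mm = sample(n),
                         .score = round(runif(n)))
    ord <- order(rp$path_mm)
    for (W in 1:n) {
      got <- antenna_grouping(rp, W = W)
      want <- mean(rp$.score[ord][1:W] >= 0.5)
      expect_equal(got$fused_score, want)
    }
  })
})

test_that("EA/MA/EAC models consume the channels their architecture dictates", {
  tt <- toy_feature_table()
  ea <- build_model(tt, "EA", 0, forest_config(50), seed = 1)
  expect_length(ea$forests, 1)
  expect_equal(ea$forests$main$n_obs, sum(tt$angle == 0))

  ma <- build_model(tt, "MA", 60, forest_config(50), seed = 1)
  expect_equal(ma$forests$main$n_obs, nrow(tt))

  eac <- build_model(tt, "EAC", 30, forest_config(50), seed = 1)
  expect_length(eac$forests, 2)
  expect_equal(names(eac$forests), c("EA_0", "EA_30"))

  expect_error(build_model(tt, "EA", 90, forest_config(50)), "no channels")

  preds <- predict_scans(eac, tt)
  expect_equal(nrow(preds), 20)
  expect_true(all(preds$fused_score >= 0 & preds$fused_score <= 1))
})

test_that("nested CV partitions scans without leakage and reports fold AUCs", {
  tt <- toy_feature_table(n_scans = 20, sep = 3)
  cv <- nested_cv(tt, "EA", 0, k = 5, config = forest_config(50), seed = 9)
  expect_equal(nrow(cv$folds), 5)
  ## union of test folds is the full scan set, each scan exactly once
  expect_setequal(cv$predictions$scan_id, unique(tt$scan_id))
  expect_equal(nrow(cv$predictions), 20)
  expect_true(all(cv$folds$n_test_scans == 4))
  expect_true(all(cv$folds$auc >= 0 & cv$folds$auc <= 1))
  ## strong separation: high AUC
  expect_gt(cv$mean_auc, 0.9)
  ## per-fold class proportions within one scan of global (here exactly 2+2)
  tab <- table(cv$predictions$fold, cv$predictions$true_label)
  expect_true(all(tab == 2))

  g <- glance(cv)
  expect_equal(g$mean_auc, cv$mean_auc)
})

test_that("majority-vote fusion beats mean per-channel accuracy when channels are informative", {
  tt <- toy_feature_table(n_scans = 30, n_channels = 9, sep = 1.2, seed = 5)
  cv <- nested_cv(tt, "MA", 60, k = 5, config = forest_config(100), seed = 7)
  chan <- cv$channel_predictions
  per_channel_acc <- mean(chan$.label == chan$label)
  grouped_acc <- mean(cv$predictions$fused_label == cv$predictions$true_label)
  if (per_channel_acc > 0.5) {
    expect_gte(grouped_acc, per_channel_acc)
  }
  succeed()
})
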