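#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run: the processing mode (TW uses the
#' 60-sample windowed signatures as classifier input, FE the 30 features of
#' the raw artefact-removed signals, TW+FE the 30 features of the windowed
#' signatures), the model architecture, antenna-grouping policy,
#' cross-validation and generator parameters. All seeds are recorded in the
#' configuration so a run is reproducible from its stored config.
#'
#' @param mode `"TW"`, `"FE"` or `"TW+FE"`.
#' @param model `"EA"`, `"MA"` or `"EAC"`.
#' @param angle EA angle or MA/EAC range upper bound, degrees.
#' @param W Antenna-grouping vote size; `NULL` uses all channels.
#' @param k Outer cross-validation folds.
#' @param threshold Decision threshold.
#' @param search_budget Hyperparameter-search budget per fold; `NULL`
#'   disables the search and uses `forest_config()` defaults.
#' @param design,glandular_fractions,noise_sigma,n_samples Generator
#'   parameters (see [generate_dataset()]).
#' @param benign_s,malignant_s Class spiculation bands.
#' @param seed Master seed for the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("TW+FE", "TW", "FE"),
                       model = c("EAC", "EA", "MA"),
                       angle = 30, W = NULL, k = 5, threshold = 0.5,
                       search_budget = NULL,
                       design = list(n_breasts = 1, n_tumours = 24,
                                     n_positions = 5),
                       glandular_fractions = 0.05,
                       noise_sigma = 0.05, n_samples = 4096,
                       benign_s = c(0, 0.25), malignant_s = c(0.50, 0.90),
                       seed = 1) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  arr <- ring_array()
  if (!angle %in% distinct_angles(arr)) {
    stop(sprintf("config error: angle %g is not a channel angle of the 12-antenna ring", angle),
         call. = FALSE)
  }
  if (model %in% c("MA", "EAC") && angle == 0) {
    stop("config error: MA/EAC ranges start at [0, 30]; use an EA model for angle 0",
         call. = FALSE)
  }
  structure(
    list(mode = mode, model = model, angle = angle, W = W, k = k,
         threshold = threshold, search_budget = search_budget,
         design = design, glandular_fractions = glandular_fractions,
         noise_sigma = noise_sigma, n_samples = n_samples,
         benign_s = benign_s, malignant_s = malignant_s, seed = seed),
    class = "run_config"
  )
}

#' Hash of a run configuration
#'
#' Stable identifier written into every output manifest so result files can
#' be traced back to the exact configuration that produced them.
#'
#' @param config A [run_config()].
#' @return A character hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rlang::hash(unclass(config))
}

#' Run the full three-stage diagnosis pipeline
#'
#' Executes scan generation, artefact removal, tumour windowing and/or
#' feature extraction per the configured mode, scan-grouped nested
#' cross-validation of the configured model, and evaluation (pooled ROC,
#' optimal threshold, feature-contribution map from a forest trained on the
#' full processed table). When `out_dir` is given, the processed table,
#' per-fold predictions, ROC points, contribution map and the configuration
#' (with its hash) are written as CSV/JSON.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `mw_run` with `config`, `hash`, `features`
#'   (processed table), `cv` ([nested_cv()] result), `roc`, `threshold`,
#'   `contribution` and `paths` (when written).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  arr <- ring_array()
  pulse <- mw_pulse()
  angles_needed <- if (config$model == "EA") config$angle else {
    a <- distinct_angles(arr)
    a[a <= config$angle]
  }

  scans <- generate_dataset(
    design = config$design,
    glandular_fractions = config$glandular_fractions,
    array = arr, pulse = pulse,
    n_samples = config$n_samples,
    noise_sigma = config$noise_sigma,
    benign_s = config$benign_s, malignant_s = config$malignant_s,
    seed = config$seed
  )

  features <- pipeline_features(scans, config$mode, angles = angles_needed)

  cv <- nested_cv(
    features, kind = config$model, angle = config$angle, k = config$k,
    search_budget = config$search_budget, W = config$W,
    threshold = config$threshold, seed = config$seed
  )
  roc <- roc_curve(cv$predictions$fused_score, cv$predictions$true_label)
  thr <- optimal_threshold(roc)

  final <- build_model(features, config$model, config$angle,
                       seed = config$seed)
  contrib <- feature_contribution_map(
    final, mode = if (config$mode == "TW") "TW" else "FE"
  )

  out <- structure(
    list(config = config, hash = config_hash(config), features = features,
         cv = cv, roc = roc, threshold = thr, contribution = contrib,
         paths = NULL),
    class = "mw_run"
  )
  if (!is.null(out_dir)) out$paths <- write_run(out, out_dir)
  out
}

#' @export
print.mw_run <- function(x, ...) {
  cat(sprintf("<mw_run> mode %s, %s %g°: mean fold AUC %.3f, pooled AUC %.3f\n",
              x$config$mode, x$config$model, x$config$angle,
              x$cv$mean_auc, attr(x$roc, "auc")))
  cat(sprintf("  optimal threshold %.3f (Youden J %.3f), config hash %s\n",
              x$threshold$threshold, x$threshold$youden_j, x$hash))
  invisible(x)
}

## processed per-channel classifier input for the requested mode
pipeline_features <- function(scans, mode, angles = NULL) {
  if (mode %in% c("TW", "TW+FE")) {
    sigs <- prepare_signatures(scans, angles = angles)
    if (mode == "TW") signature_table(sigs) else extract_feature_table(sigs)
  } else {
    raw_feature_table(scans, angles = angles)
  }
}

## FE mode: features of the raw (artefact-removed, un-windowed) signals
raw_feature_table <- function(scans, angles = NULL) {
  stopifnot(inherits(scans, "scan_set"))
  array <- attr(scans, "array")
  pulse <- attr(scans, "pulse")
  fs <- attr(scans, "fs")
  channels <- attr(scans, "channels")
  keep <- if (is.null(angles)) rep(TRUE, nrow(channels)) else channels$angle %in% angles
  ch <- channels[keep, , drop = FALSE]
  refs <- reference_bank(ch, scans, array, pulse, fs)
  rows <- lapply(seq_len(nrow(scans)), function(i) {
    scan <- scans[i, ]
    sig <- scan$signals[[1]][keep, , drop = FALSE] - refs
    p <- c(scan$pos_x, scan$pos_y)
    m <- do.call(rbind, lapply(seq_len(nrow(ch)), function(j) {
      extract_features(sig[j, ], fs = fs)
    }))
    dplyr::bind_cols(
      tibble::tibble(
        scan_id = scan$scan_id, label = scan$label,
        glandular_fraction = scan$glandular_fraction,
        tumour_id = scan$tumour_id, site = scan$site,
        tx = ch$tx, rx = ch$rx, angle = ch$angle,
        path_mm = channel_path_mm(ch, p, array)
      ),
      tibble::as_tibble(m)
    )
  })
  dplyr::bind_rows(rows)
}

## write the result bundle; returns named vector of paths
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    config = file.path(out_dir, "config.json"),
    features = file.path(out_dir, "features.csv"),
    predictions = file.path(out_dir, "predictions.csv"),
    folds = file.path(out_dir, "folds.csv"),
    roc = file.path(out_dir, "roc.csv"),
    contribution = file.path(out_dir, "contribution.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  cfg <- unclass(run$config)
  cfg$hash <- run$hash
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  readr::write_csv(run$features, paths["features"])
  readr::write_csv(run$cv$predictions, paths["predictions"])
  readr::write_csv(run$cv$folds, paths["folds"])
  readr::write_csv(tidy(run$roc), paths["roc"])
  readr::write_csv(tibble::as_tibble(run$contribution), paths["contribution"])
  jsonlite::write_json(
    list(hash = run$hash, files = basename(unname(paths))),
    paths["manifest"], auto_unbox = TRUE, pretty = TRUE
  )
  paths
}

#' Write and read feature tables with bit-exact round-tripping
#'
#' Doubles are serialised with 17 significant digits, enough to reproduce
#' every IEEE double exactly on re-parse, so a written feature table reads
#' back bit-identical.
#'
#' @param x A feature (or signature) table.
#' @param path CSV path.
#' @return `write_feature_csv()` returns `path` invisibly;
#'   `read_feature_csv()` the parsed tibble.
#' @export
write_feature_csv <- function(x, path) {
  out <- x
  for (cn in names(out)) {
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  ## base parser: exact strtod round-trip of the %.17g serialisation
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  ## predictor columns are real-valued by schema even when integer-valued
  for (cn in grep("^[tf][0-9]{2}$", names(out), value = TRUE)) {
    out[[cn]] <- as.double(out[[cn]])
  }
  out
}

#' Write a scan set as plain-text files
#'
#' One CSV per scan (channels x samples, one row per channel prefixed by
#' `tx`, `rx`) plus a JSON sidecar holding the scan metadata, the array
#' geometry (antenna positions in mm) and the generator parameters.
#'
#' @param scans A [generate_dataset()] scan set.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_scan_set <- function(scans, dir) {
  stopifnot(inherits(scans, "scan_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arr <- attr(scans, "array")
  channels <- attr(scans, "channels")
  meta <- list(
    fs = attr(scans, "fs"), n_samples = attr(scans, "n_samples"),
    design = attr(scans, "design"), seed = attr(scans, "seed"),
    geometry = list(radius = arr$radius, centre = arr$centre,
                    positions = unname(apply(arr$positions, 1, as.numeric,
                                             simplify = FALSE))),
    scans = lapply(seq_len(nrow(scans)), function(i) {
      s <- scans[i, ]
      list(scan_id = s$scan_id, label = s$label, s = s$s,
           diameter = s$diameter, site = s$site,
           position = c(s$pos_x, s$pos_y),
           glandular_fraction = s$glandular_fraction, seed = s$scan_seed)
    })
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_len(nrow(scans))) {
    m <- scans$signals[[i]]
    colnames(m) <- sprintf("s%05d", seq_len(ncol(m)))
    d <- dplyr::bind_cols(channels[, c("tx", "rx")], tibble::as_tibble(m))
    write_feature_csv(d, file.path(dir, paste0(scans$scan_id[i], ".csv")))
  }
  invisible(dir)
}

#' Read a scan-set signal matrix written by [write_scan_set()]
#'
#' @param dir Directory written by [write_scan_set()].
#' @param scan_id Scan to read.
#' @return The channels x samples signal matrix.
#' @export
read_scan_signals <- function(dir, scan_id) {
  d <- utils::read.csv(file.path(dir, paste0(scan_id, ".csv")))
  m <- as.matrix(d[, -(1:2)])
  storage.mode(m) <- "double"
  m
}
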