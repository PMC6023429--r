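Package: mwdiagnosis
Title: Multistatic Microwave Breast Scan Simulation and Random-Forest Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for studying machine-learning diagnosis of breast tumours
    from ultra-wideband microwave backscatter. Provides a 12-antenna
    multistatic ring-array geometry model, a synthetic scan generator that
    emulates skin reflection, geometry-delayed tumour echoes with
    spiculation-controlled waveform distortion and glandular clutter, a
    tumour-signature windowing stage (three-media round-trip delay,
    peak-energy time alignment, anti-aliased downsampling to 60-sample
    signatures), a 30-descriptor feature bank (time-domain peak statistics,
    autocorrelation and power-spectral-density features), random-forest
    classifiers organised into equal-angle, multiple-angle and combined
    channel architectures with ranked antenna-grouping majority voting,
    out-of-bag hyperparameter optimisation, scan-grouped stratified nested
    cross-validation, and ROC/AUC evaluation with feature-contribution maps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
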