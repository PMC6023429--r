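# mwdiagnosis

Simulation and machine-learning diagnosis of breast tumours from
ultra-wideband microwave backscatter.

Microwave breast imaging records the energy scattered back when the breast is
illuminated with low-power microwaves. Because malignant tumours carry
spiculated (spiky) margins while benign ones are smooth, the shape of the
tumour leaves a fingerprint in the backscattered waveform: smooth tumours
return a clean copy of the interrogating pulse, spiculated tumours a
distorted, multi-peaked superposition. `mwdiagnosis` implements the full
three-stage computer-aided diagnosis platform that exploits this:

1. **Acquisition (simulated).** A ring of 12 point antennas (adjacent
   spacing 30°) scans the breast in a fully multistatic fashion, giving
   n(n+1)/2 = 78 transmit–receive channels per scan. A synthetic scan
   generator replaces the electromagnetic solver: each channel signal is the
   superposition of the antenna-coupling reference, a dominant skin
   reflection, a geometry-delayed tumour echo whose distortion grows with
   the spiculation parameter *s* (benign 0 ≤ s ≤ 0.25, malignant
   0.50 ≤ s ≤ 0.90), glandular clutter scaling with the glandular fraction,
   and white noise — sampled at 600 GHz.
2. **Signal processing.** Tumour windowing (TW): reference subtraction, the
   three-media round-trip delay τ = Σ ℓᵢ√εᵢ/c over both legs of the
   Tx→tumour→Rx path, a window of 2.5 pulse widths around the arrival,
   peak-energy time alignment, and anti-aliased downsampling to 60-sample
   signatures at 30 GHz. Feature extraction (FE): 30 descriptors per signal
   in four sub-groups — time-domain peak/area statistics (#1–#19),
   autocorrelation peak statistics (#20–#24), Welch and periodogram spectral
   statistics (#25–#30).
3. **Diagnosis.** Random forests classify each channel independently;
   channel-angle architectures (EA = one angle, MA = pooled angle range,
   EAC = per-angle EA members fused by majority vote) test whether the
   Tx–Rx angular separation Z ∈ {0°, 30°, …, 180°} determines predictive
   power. A ranked antenna-grouping majority vote over the W channels
   closest to the tumour turns per-channel votes into one diagnosis per
   scan. Hyperparameters (trees, features per split, leaf size) are tuned
   on the out-of-bag error; validation uses scan-grouped stratified nested
   cross-validation; performance is reported as ROC/AUC with
   feature-contribution maps.

## Worked example

```r
library(mwdiagnosis)

cfg <- run_config(
  mode  = "TW+FE",          # features of the windowed signatures
  model = "EAC", angle = 30, # combine the EA 0° and EA 30° members
  k = 5,
  design = list(n_breasts = 1, n_tumours = 12, n_positions = 2),
  glandular_fractions = 0.05,
  seed = 42
)
run <- run_pipeline(cfg)
run
#> <mw_run> mode TW+FE, EAC 30°: mean fold AUC 1.000, pooled AUC 1.000
#>   optimal threshold 0.708 (Youden J 1.000), config hash bec7ac7c5f1bb3ed23316a6a...

glance(run$cv)
#> # A tibble: 1 × 5
#>   kind  angle     k mean_auc sd_auc
#> 1 EAC      30     5        1      0

head(run$cv$predictions)
#> # A tibble: 6 × 6
#>   scan_id  fused_score fused_label w_used true_label  fold
#> 1 scan0001       0.292 benign          24 benign         1
#> 2 scan0004       0.208 benign          24 benign         1
#> 3 scan0011       0     benign          24 benign         1
#> 4 scan0016       0.792 malignant       24 malignant      1
#> ...
```

Each row is one scan-level diagnosis: `fused_score` is the fraction of
malignant votes among the `w_used` per-channel forest predictions entering
the antenna-grouping majority vote, and `fused_label` applies the decision
threshold. On this small high-contrast dataset the spiculation signal is
strong enough that every test fold is ranked perfectly (AUC 1), and the
contribution map shows the forests leaning on the absolute integral (#17),
the peak counts (#7, #8) and the signal variance (#5) — descriptors that
directly track waveform distortion:

```r
head(dplyr::arrange(run$contribution, dplyr::desc(contribution)), 5)
#>   term  contribution mode
#> 1 f17          1     FE
#> 2 f08          0.787 FE
#> 3 f07          0.532 FE
#> 4 f26          0.402 FE
#> 5 f05          0.388 FE

autoplot(run$roc)                 # pooled ROC curve
autoplot(run$contribution)        # feature-contribution bar map
```

## Package layout

| Area | Functions |
| --- | --- |
| Array geometry | `ring_array()`, `enumerate_channels()`, `channel_angle()`, `distinct_angles()`, `rank_channels_by_proximity()`, `model_families()` |
| Synthetic scans | `mw_pulse()`, `breast_spec()`, `tumour_spec()`, `sample_tumour()`, `simulate_reference()`, `simulate_channel_signal()`, `simulate_scan()`, `generate_dataset()` |
| Signal processing | `media_model()`, `remove_artifact()`, `roundtrip_delay()`, `window_tumour()`, `align_and_downsample()`, `prepare_signatures()`, `signature_table()` |
| Feature bank | `detect_peaks()`, `time_features()`, `autocorr_features()`, `psd_features()`, `extract_features()`, `extract_feature_table()` |
| Diagnosis | `forest_config()`, `train_forest()`, `optimise_hyperparameters()`, `build_model()`, `predict_scans()`, `antenna_grouping()`, `make_folds()`, `nested_cv()` |
| Evaluation | `roc_curve()`, `roc_auc()`, `optimal_threshold()`, `feature_contribution_map()`, `autoplot()` methods, `tidy()`/`glance()` methods |
| Pipeline & I/O | `run_config()`, `run_pipeline()`, `write_scan_set()`, `write_feature_csv()` |

See `vignettes/microwave-diagnosis.Rmd` for the methods account: the echo
model and its assumptions, parameter defaults and units, numerical choices,
and known limitations.
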