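---
title: "Microwave breast diagnosis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microwave breast diagnosis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwdiagnosis)
```

`mwdiagnosis` studies whether the *shape* of a breast tumour — smooth and
well-circumscribed in benign disease, spiculated in malignancy — can be read
off ultra-wideband microwave backscatter by a random-forest classifier. This
vignette is the package's methods account: the signal model behind the
synthetic scan generator, the processing and classification stages, every
tunable parameter with its default and units, the numerical choices, and
what the package's passing tests do and do not establish about real data.

## 1. Acquisition geometry

The scanner is modelled as a planar (coronal-slice) ring of `n = 12` point
antennas at radius 70 mm, antenna 0 at polar angle 0°, numbered
counter-clockwise; adjacent antennas are 360/12 = 30° apart. A fully
multistatic scan records one signal per unordered transmit–receive pair
including the monostatic pairs, i.e. `n(n+1)/2 = 78` channels. The *channel
angle* `Z = min(|tx − rx|, n − |tx − rx|) · 360/n` takes the seven values
{0°, 30°, …, 180°}: twelve channels at each angle below 180° and six at
180°.

Channel-to-tumour *proximity* is measured by the two-leg path
`|Tx − p| + |p − Rx|`: it is the physical propagation path of the tumour
echo and reduces to twice the antenna–tumour distance for monostatic
channels. Ties (e.g. a tumour exactly at the centre, where every channel's
path is `2r`) are broken lexicographically by `(tx, rx)`, keeping the
ranking deterministic and seed-free.

The ring radius is a free geometry parameter (the acquisition literature
varies here); 70 mm leaves a 20 mm immersion gap around the default 50 mm
breast.

## 2. The synthetic scan generator

The generator replaces a full-wave electromagnetic solver with a geometric
echo model. This is deliberate: the diagnosis pipeline consumes only time
signals, and the discriminative mechanism under study — waveform distortion
growing with margin spiculation — can be reproduced by superposing delayed
pulse copies. The generator's defaults *are* the study conditions; they are
chosen once and the tests run against them.

**Excitation.** A differentiated Gaussian pulse. Its amplitude spectrum
`|F(f)| ∝ f e^{−2π²σ²f²}` peaks at `1/(2πσ)`, so σ is set from the 6 GHz
centre frequency (σ ≈ 26.5 ps). The *nominal pulse width*
`width_tp = 0.8 ns` is the windowing time unit: a 2.5-pulse-width window at
the 600 GHz acquisition rate holds 1200 raw samples and downsamples by 20
to exactly the 60-sample signature the classifiers consume.

**Breast.** A circular section of radius 50 mm with a 2 mm skin annulus,
immersed in an adipose-matched medium. Relative permittivities default to
9 (immersion), 36 (skin), 12 (interior) — representative low-GHz values for
adipose-dominated tissue, water-rich skin, and a mildly glandular interior.
The glandular fraction presets are 1%, 5% and 27% by volume.

**Per-channel signal.** Each channel superposes:

* the deterministic antenna-coupling *reference* (direct Tx→Rx pulse through
  the immersion medium, amplitude `1/(1 + d)` with `d` the antenna
  separation; identical for channels of equal angle, self-coupling at zero
  delay for monostatic ones);
* a *skin reflection* at the specular entry points towards the breast
  centre, with amplitude `skin_ratio = 15` times the principal tumour echo —
  preserving the amplitude ordering of real scans, where the skin response
  is orders of magnitude above the tumour signature;
* the *tumour response*: a pulse copy at the three-media round-trip delay
  (Section 3) with path-loss amplitude `1/(1 + path length in mm)`, plus
  `k ~ Poisson(round(10·s))` spicule sub-echoes at uniform delay offsets
  within ±1 pulse width and uniform amplitudes in [0.2, 0.8] of the
  principal. The intensity law λ = 10·s makes benign tumours
  (s ∈ [0, 0.25], λ ≤ 2–3) nearly clean and malignant ones
  (s ∈ [0.50, 0.90], λ = 5–9) strongly multi-peaked — separable but
  overlapping classes;
* *glandular clutter*: `Poisson(20 · glandular_fraction)` echoes from
  uniformly drawn interior points, amplitudes uniform in [0.05, 0.5] of the
  principal — monotone in the heterogeneity presets;
* additive white Gaussian noise with σ = `noise_sigma` (default 0.05)
  relative to the principal echo amplitude.

The record is 4096 samples at 600 GHz (≈ 6.8 ns), enough for every
round-trip delay of the default geometry. Tumour diameters are uniform in
[6, 20] mm; spiculation is drawn uniformly from the class band. The default
design crosses 3 breast presets × 72 tumour models (36 benign/36 malignant,
drawn once and reused) × 5 positions — the central portion and the four
quadrants at half the breast radius along the ±45° diagonals — giving 1080
scans and 84,240 signals. Everything is reproducible from a single integer
seed.

**What the generator does not emulate:** full-wave propagation (dispersion,
multiple scattering, antenna patterns), anatomically realistic glandular
structure, 3-D geometry, and any systematic coupling between tumour *size*
and its echo beyond path loss. Tests passing on this generator show the
pipeline recovers the planted spiculation→distortion mechanism under
realistic amplitude orderings and noise; they do not certify performance on
clinical or experimental data.

## 3. Tumour windowing

The round-trip delay is computed on the straight ray through the three
media: the segment lengths in immersion, skin and interior (line–circle
intersections) are divided by the per-medium speed `c/√ε` and summed over
both legs. The true tumour position from the scan metadata is used — the
idealised-localisation setting; localisation error is out of scope.

The window spans 2.5 pulse widths (1200 raw samples) starting at
`delay − 0.75 · width_tp`: asymmetric on purpose, because spicule sub-echoes
trail the principal echo. Windows overrunning the record are zero-padded
with a warning.

Downsampling 600 → 30 GHz applies a 385-tap zero-phase FIR low-pass with
cutoff at the 15 GHz output Nyquist before keeping every 20th sample —
naive decimation would alias the upper band edge of the 6 GHz-centred
pulse. The tap count keeps the passband genuinely flat through ~12 GHz
(verified against an ideal-filter oracle at <1% L2 error on band-limited
inputs).

*Peak energy* is read as the sample of maximum absolute amplitude (the
simplest interpretation; an envelope or sliding-energy variant would be a
drop-in replacement). Alignment is per signal: the 60-sample signature is
circularly shifted so its peak lands on sample 34 (1-based) — the location
the time-window classifiers are reported to lean on. Two deliberate
implementation choices here: the peak is located *after* filtering and
decimation, so the invariant "the signature's maximum magnitude sits at the
alignment index" holds exactly and re-aligning an aligned signature is the
identity; and an all-zero window keeps the same alignment index, flagged
`low_quality`, rather than a special centre index — one constant instead of
two. A note on degeneracy: a lone differentiated Gaussian has two extrema
of exactly equal magnitude, so for perfectly clean symmetric echoes the
peak choice is decided by floating-point noise; any physical asymmetry
(sub-echoes, clutter, noise) removes the tie.

## 4. The feature bank

Thirty descriptors per signal, each depending only on that signal — no
cross-observation computation, so feature extraction cannot leak
information between training and test sets. Peak analysis underlies most of
them: strict local maxima filtered by topographic prominence (default
threshold 5% of the signal's maximum magnitude, suppressing numerical
ripple), with widths measured by linear interpolation at half the peak's
prominence-referenced height and clipped at the window edges.

* **Time domain (#1–#19)**, on the 60-sample signature (units: amplitude,
  sample indices, ns): extreme positive/negative peak amplitudes and
  locations (#1–#4); variance (#5); RMS value (#6 — the "root-mean-squared
  error" of the original table names no reference waveform, so the RMS of
  the signal is used); peak counts, mean amplitudes, mean FWHMs per polarity
  (#7–#12); mean *within-polarity* separation of consecutive peaks
  (#13–#14 — the parallel reading of the per-polarity structure of
  #11–#12); zero crossings (#15); discrete integrals of the signal and its
  magnitude (#16–#17); positive/negative percentage areas (#18–#19).
* **Autocorrelation (#20–#24)**: the linear autocorrelation over
  non-negative lags, normalised to 1 at lag 0 (computed via FFT, equal to
  the definitional sums to 1e−10); its mean and the count/amplitude/FWHM/
  separation statistics of its peaks, lag-0 endpoint excluded.
* **Spectral (#25–#30)**, at 30 GHz: mean of a Welch estimate — Hann
  window, segment length 30, 50% overlap, i.e. three segments on a
  60-sample record (no canonical parameters exist for records this short;
  these give the minimal stable average) — and mean, peak count, peak
  amplitude, peak FWHM (frequency bins) and peak separation of the
  full-length rectangular periodogram. One-sided estimates normalised so
  the integrated PSD equals the mean signal power (Parseval-consistent).

Degenerate inputs map to defined defaults (zero counts and means), so every
feature vector is finite. Scale behaviour is as the definitions imply
(amplitudes and integrals scale linearly, variance quadratically; counts,
locations and normalised-autocorrelation features are scale-invariant), and
the spectral/autocorrelation features are shift-insensitive up to the edge
effects of a finite record — the linear (not circular) autocorrelation and
the sliding Welch segments see slightly different content after a circular
shift, which bounds rather than nullifies the invariance.

## 5. Diagnosis

Each `(scan, channel)` signature or feature vector is one training row
labelled with its scan's class; per-channel predictions are fused only at
diagnosis time. Random forests (via `ranger`) grow each tree on a bootstrap
sample — leaving about one third of rows out-of-bag — with random feature
subsets; OOB misclassification is the model-selection criterion and OOB
permutation importance feeds the contribution maps (permutation rather than
impurity importance: less biased under correlated inputs, which both
signature samples and spectral features are).

Hyperparameters `{n_trees ∈ [50, 500], mtry ∈ [1, p], min leaf ∈ [1, 20]}`
are tuned by a small sequential model-based search: a maximin
Latin-hypercube initial design covering half the budget, then a
random-forest surrogate proposing each next candidate by minimum predicted
OOB error; ties in the final selection go to fewer trees. The search is
seed-deterministic. (Any optimiser minimising the same OOB criterion is
interchangeable here.)

The channel-angle architectures: **EA** trains one forest on channels of a
single angle Z; **MA** pools all channels with angle ≤ the range bound;
**EAC** holds one EA member per angle in the range and fuses the members'
*scan-level* decisions by unweighted majority. Fusion order inside EAC is a
genuinely open choice — members could pool channel votes first or vote as
models first; the package lets each member apply its own antenna grouping
first, so every member contributes exactly one opinion per scan regardless
of how many channels it owns. For ROC purposes the EAC score is the mean of
the member fused scores.

**Antenna grouping**: among the W channels closest to the tumour (two-leg
path ranking; all channels by default), the fused score is the fraction of
malignant votes, and ties resolve to malignant — favouring sensitivity in a
screening context. Both the threshold (default 0.5) and the tie rule are
configurable.

**Validation**: stratified k-fold (default k = 5) nested cross-validation
at *scan* level — all 78 channels of a scan stay on one side of every
split, and the train/test scan sets are asserted disjoint on every fold.
Hyperparameter search, when enabled, runs inside each training fold only,
on the OOB criterion (no inner CV loop is needed since OOB already
estimates generalisation); for EAC the per-fold search runs once on the
pooled member rows and the chosen configuration is shared by the members.
Reported performance is the mean AUC over the outer test folds.

## 6. Evaluation

The ROC curve sweeps the decision threshold over the unique fused scores;
AUC is the trapezoidal area, identical to the Mann–Whitney rank statistic
with ties credited ½ (asserted against the pairwise oracle, and
cross-checked against an independent ROC implementation). The optimal
threshold maximises Youden's J = TPR − FPR, ties resolving to the lower
(more sensitive) threshold. Contribution maps are max-normalised by default
(sum-normalisation available) over zero-clipped permutation importances.

On this generator, time-window models concentrate their contributions in
the neighbourhood of the alignment index rather than exactly on it: the
principal-echo amplitude itself carries little class information here (path
loss affects both classes alike), while the distortion *around* the aligned
peak does. Exact single-sample dominance is a property of data this
generator does not claim to reproduce.

## 7. Problem sizes used by the shipped checks

The test-suite and the acceptance script run, as the package's chosen study
sizes: the full default design (1080 scans) at a 64-sample record for the
count checks (counts are record-length independent); a high-contrast design
of 1 breast preset (5% glandular) × 24 tumours × 5 positions at the full
4096-sample record for the nested-CV performance checks (EAC 0–30°,
all-channel grouping, per-fold search budget 5); ten label permutations of
that dataset for the null check; and a 24-tumour × 2-position design, EA 0°
with a fixed 100-tree configuration and 5 seeds per condition, for the
spiculation-gap sweep (malignant lower bound 0.3/0.5/0.7 against the fixed
benign band).

## 8. Known limitations

* The echo model is geometric; none of the wave phenomena that complicate
  real scans (dispersion, multiple scattering, antenna coupling drift) are
  represented, and performance numbers on synthetic data are upper bounds
  rather than clinical estimates.
* Proximity ranking uses the true tumour position, as does windowing; a
  deployable system would need a localisation front end, whose errors would
  degrade both.
* The spicule-intensity, clutter and path-loss laws are simple
  parameterisations exposed in the generator config, not fitted to
  measurements.
* Monostatic (Z = 0°) channels are included as recorded signals; hardware
  that cannot transmit and receive simultaneously would synthesise or drop
  them.
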