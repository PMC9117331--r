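---
title: "Models and methods: analyzing multiplexed reporter drug screens"
author: "pathscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: analyzing multiplexed reporter drug screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experimental system this package models

pathscreen analyzes pooled live-cell reporter screens in which a dozen
clonal reporter lines are mixed in every well of a drug plate. Each
clone carries (i) a nuclear marker, (ii) a *visual barcode* — a
fluorescent protein targeted to a specific subcellular compartment,
whose (fluorophore, localization) pair identifies the clone in images —
and (iii) a live reporter for one signaling pathway. Two reporter types
occur: kinase translocation reporters (KTR), read out as the per-cell
cytoplasm/nucleus mean-intensity ratio, and transcription-response-
element (TRE) reporters, read out as the background-subtracted mean
nuclear intensity.

The pipeline runs: synthetic data generation → image segmentation and
barcode calling → signed-KS activity scoring → signaling-state analysis
(clustering, PCA metrics) → drug-target ridge deconvolution → growth /
division homeostasis fitting → cohort correlation-structure comparison.
Every stage is usable on its own; `run_pipeline()` drives the chain.

# The synthetic-data generator

Because raw screen data of this kind are not packaged as machine-readable
inputs, all downstream stages are developed and validated against a
generator with planted ground truth. The generator defines the study
conditions; its defaults are not tuning knobs.

## Barcode images

`simulate_barcode_images()` renders, per clone, multi-channel fields:
a nuclear-marker channel, a phase-contrast-like body channel (the
segmentation substrate), and one channel per fluorophore. Geometry
choices: cells are random ellipses of 300–1200 px area (axis ratio
0.55–0.95), nuclei are concentric ellipses at 30% of the cell area,
the endoplasmic-reticulum pattern is a perinuclear annulus 3 px wide,
and peroxisomes are 5–20 bright puncta of radius 1–2 px in the
cytoplasm. These geometric parameters were chosen once so that the five
localization classes are separable but not trivially so; they are not
revisited per experiment. Pixel noise is Poisson shot noise at a finite
photon budget plus Gaussian read noise over a uniform background
(`noise_params()`: 400 photons at unit intensity, read SD 0.01,
background 0.03); `noise = 0` disables all three for exactness tests.
Images use a 0-based (row, col) pixel convention and are written as
16-bit multi-page TIFF.

What the image generator does *not* emulate: optics (point-spread
function, spectral bleed-through), cell motility, lineage, confluent
monolayers, or illumination gradients. Classifier error rates measured
on these images therefore demonstrate that the calling machinery works,
not that any particular error rate transfers to real microscopy.

## The pooled screen

`screen_design()` encodes the planted structure:

* 12 reporters (5 KTR, 7 TRE), pooled in every well;
* a unit *state axis* `u` over pathways with opposite signs on the two
  planted clusters — the five kinase reporters (+) against six
  stress/transcription reporters (−), with the cell-cycle reporter
  off-axis — so that drugs acting through the shared axis produce two
  anticorrelated response programs;
* 100 drugs by default: 40 loading positively on `u` (the
  growth-limiting program), 40 negatively (the division-limiting
  program), 20 off-axis drugs whose effect vector is drawn orthogonal
  to `u` (norm 1–2);
* per-drug effects `w_d(t) = ramp_state(t) * s_d * u + ramp_direct(t) * e_d`
  in units of the latent per-cell SD, with `|s_d| ~ U(1, 3)` and
  idiosyncratic SD 0.15 for on-axis drugs;
* 39 DMSO control wells, 3 replicate wells per drug, timepoints
  0/12/24/36/48 h, Poisson(200) cells per clone per well — a sampling
  depth of roughly 600 cells per reporter per condition, matching the
  hundreds-of-cells regime of real plates;
* well nuisance: a scalar per-well shift (SD 0.05) common to all
  reporters, plus a per-well shift along `u` (SD 0.10) that plants
  state structure already at t = 0.

Two deliberate dynamic choices need explanation. First, the two effect
components ramp differently: the drug-specific direct component rises
as a saturating exponential with a 2 h constant (direct reporter
responses are fast — an upstream kinase inhibitor moves its reporter
within the first imaging interval), whereas the shared-state component
rises with the sigmoidal onset `(1 - exp(-t/12 h))^2`. A single shared
exponential ramp would make the state axis statistically visible within
the first hour, which contradicts the characteristic homeostatic
dynamics this generator is meant to emulate: pre-existing correlated
activity is *eliminated* in the first hour of treatment and the
drug-driven states gain prominence only over the following 48 h.
Second, for the same reason, the spontaneous well-state component
decays in treated wells with a 0.5 h constant (`state_decay`): the
perturbation overrides the well's spontaneous state, after which fresh
sampling noise dominates until the drug-driven state emerges. Control
wells keep their state. With these choices the variance-product metric
phi (below) reproduces the dip-then-gain trajectory: near its
pre-treatment value at t = 0, rising toward 1 immediately
post-perturbation, then falling as the state response grows.

Per-cell readout distributions are stand-ins — no per-cell distribution
family is published for these reporters. KTR ratios are a logistic
transform of a unit-SD latent Gaussian mapped onto (0.2, 4), giving a
bounded, positive, heavy-enough-tailed ratio; TRE intensities are
lognormal (`100 * exp(0.4 z)`). Drug effects shift the latent location.
No claim is made that these families match any real cell line's
biology; all recovery results should be read as "the estimators recover
what was planted under plausible noise", not as biological validation.

Growth-coupling ground truth: a drug with state weight `s` gets
`gamma_d = gamma_0 * 2^(-0.30 s⁺ - 0.05 s⁻)` and
`alpha_d = alpha_0 * 2^(-0.10 s⁺ - 0.35 s⁻)` (γ = per-cell mass
accumulation rate, α = division rate; controls γ₀ = ln2/20 h⁻¹,
α₀ = ln2/22 h⁻¹). Positive-state drugs are thus growth-limited
(imbalance < 0, smaller cells), negative-state drugs division-limited
(larger cells), and mean cell size scales with `(gamma/alpha)`
relative to control around 650 px. The asymmetric exponents encode
*incomplete compensation*: the non-targeted rate adapts, but not fully.

All generators fan a single master seed out to per-stage child seeds
(below 2^31), so everything is bit-reproducible.

# Barcode calling

`segment_cells()` detects nuclei on the smoothed (σ = 2 px) nuclear
channel by Otsu thresholding, splits touching nuclei with a
distance-transform watershed, and grows cells from nucleus seeds over
the body channel. Tertiary compartments per cell: perinuclear ring
(3 px around the nucleus), cytoplasm (cell − nucleus − ring, so
compartments are disjoint), and a cell-specific background annulus
2–5 px outside the cell excluding all cells (its median/mean feeds
background subtraction). Objects under 20 px (nuclei) / 60 px (cells)
are dropped. The whole stage is deterministic.

`extract_features()` builds the cytological profile: per compartment ×
channel intensity statistics and integrated intensities, Haralick
co-occurrence texture over the cell mask, shape and moment descriptors,
the per-channel similarity-to-nucleus correlation (the within-cell
Pearson correlation of a channel with the nuclear marker — high for
nuclear localization, low for cytoplasmic), nucleus/cytoplasm mean
ratios, and background-corrected nuclear means. With the default six
channels this exceeds 200 features. Missing entries from empty
compartments are imputed with the column median.

`train_barcode_classifier()` fits a boosted ensemble of shallow trees
(depth 2, 50 stages, learning rate 0.3) on a stratified 70/30 split —
the additive-rules model class, with the stage budget as the capacity
contract. Training demands ≥ 200 cells per class, and retraining per
experiment is the intended use (reusing rules across experiments
degrades accuracy). `call_barcodes()` matches features by name and
returns the class plus a confidence (max class probability); note that
tree ensembles give saturated confidences for cells deep inside a
trained class's region — an unseen clone is flagged by low confidence
only when its profile conflicts between trained classes.
`confusion_metrics()` reports, per predicted class, the false detection
rate FP/(FP+TP) and, per true class, the miss rate FN/(FN+TP), with
macro averages; classes never predicted have undefined (NA) FDR.

On the default 12-clone synthetic panel (300 cells/clone, default
noise) the validation macro FDR and miss rate are both ≈ 0.1–0.2%, and
the rare confusions occur between clones sharing a fluorophore, as the
acceptance suite checks.

# Signed-KS activity scoring

For each (drug, reporter, timepoint) group, `score_screen()` compares
the treated cells' readout distribution with the pooled time-matched
DMSO cells of the same clone:

* the magnitude is the two-sample Kolmogorov–Smirnov statistic `D`
  (`ks_statistic()`, a merged-sort scan with exact tie handling,
  oracle-checked against a brute-force ECDF scan);
* the sign is +1/−1 by the treated-vs-control median shift, falling
  back to the mean difference on a median tie, and 0 if both tie. The
  median is the non-interpolating order statistic (type-1 quantile) so
  that the score — like `D` itself — is exactly invariant under
  strictly increasing transforms of both samples.

Scores live in [−1, 1]; a score is invalid when either side has fewer
than 30 cells. Control pooling (all same-timepoint DMSO wells, per
clone) maximizes the control sample; per-well control matching is not
used. `derive_threshold()` takes the 99.5th percentile of |score| over
control-vs-remaining-control scores — the extreme half-percent tail of
the null — with R's default type-7 linear-interpolation quantile, fixed
and documented; the conventional fallback threshold is ±0.2.
`active_drugs()` flags drugs with any valid post-treatment |score|
above the threshold. KS saturates for large shifts (D ≤ 1), so strong
effects compress near ±1; trend statements about correlations over
time are therefore made with rank (Kendall) statistics.

# Signaling-state analysis

`cluster_drugs()`: Euclidean distance, Ward linkage in the squared-
distance convention ("ward.D2"), k = 3 by default (two anticorrelated
state clusters plus a remainder); pathways with missing scores are
dropped listwise first. `pathway_correlations()` gives the pairwise
Pearson matrix (pairwise-complete); `correlation_timecourse()` tracks
its mean absolute off-diagonal per timepoint with a Kendall trend
statistic.

`fit_pca()` is column-centered, unscaled PCA via SVD — scores share the
[−1, 1] scale, so variance scaling would distort relative effect sizes.
Component signs are fixed deterministically (largest-|loading| entry
positive), and PC1 can be oriented along a supplied direction so that
which state maps to positive PC1 is reproducible and configurable.

Per-drug metrics over the PC coordinates `PC_i`:

* conformity `psi = PC1 / sqrt(sum PC_i^2)` in [−1, 1];
* adherence `|PC1| / sum PC_i^2`, exactly as conventionally printed.
  As printed this is scale-dependent (halving all coordinates doubles
  it); the scale-free variant `|PC1| / sqrt(sum PC_i^2)` is available
  via `normalized = TRUE` but is never silently substituted;
* strength `sqrt(sum PC_i^2)`, the rotation-invariant norm of the
  centered effect signature.

The persistence metric `phi_metric()` compares a *reference* basis
(PCA of pre-treatment measurements) against new data: the product of
per-axis variances of the data projected onto the reference basis,
divided by the product of variances on the raw pathway axes, computed
in log space to avoid underflow of the raw products. phi = 1 exactly
when the reference is the identity basis; on the data's own eigenbasis
it equals det(covariance)/∏ variances ≤ 1 (Hadamard's inequality), and
that eigenbasis minimizes phi over orthonormal bases — both properties
are verified against brute-force determinants and random-rotation
searches in the test suite. Zero variance on any axis leaves phi
undefined (error), rather than silently clipped.

# Drug-target deconvolution

`build_design()` turns drug→target annotations into indicator columns
plus product columns for unordered target pairs co-annotated in at
least one compound (higher-order interactions are out of scope).
`ridge_solve()` minimizes

    sum_i (y_i - sum_j x_ij beta_j)^2 + lambda sum_j v_j beta_j^2

with `v_j = 1` on individual targets and `v_j = v ≥ 1` on interaction
columns, in closed form via the normal equations with diagonal penalty.
Two conventions are supported: the default centers columns and response
(unpenalized intercept); `intercept = FALSE` solves the raw loss as
written, with no constant term — in that convention a single predictor
gives the textbook `sum(xy)/(sum(x^2)+lambda)`.

`cv_select()` grid-searches (lambda, v) by 5-fold cross-validation:
`v` doubles from 1 to 2^30, and lambda spans a fixed, documented
data-driven grid (50 log-spaced values from `max|X_c' y_c|` down four
decades — the usual ridge-path construction, stated explicitly rather
than inherited from any particular library's default). Folds are a
seeded random partition stratified by response quantile. If the
held-out error is still decreasing (or exactly flat, to a 1e-10
relative tolerance — v = 2^28 and 2^30 are numerically identical once
the interaction coefficients have vanished) at the v boundary, the
interaction columns are dropped and the model refit over lambda alone,
with `interactions_dropped` set. Only individual-target coefficients
are reported by `target_effects()`; interaction terms are nuisance
structure. Whether the response should be standardized is left to the
caller — responses (PC1, cell-size change, division rate) arrive on
heterogeneous scales.

# Growth and division

`fit_division()` fits `ln N(t)` by pooled unweighted least squares over
all replicate points, giving the division rate α (1/h) and cycle length
τ = ln2/α; `fit_growth()` adds the mean-cell-mass channel
`m(t) = M(t)/N(t)` and reports the total per-cell synthesis rate
`gamma = d ln m/dt + alpha`, which equals α in balanced growth. Fitting
in log space keeps the estimators closed-form and robust at desk scale;
the population mass growth rate (`d ln M/dt`) is recoverable as the
same quantity and both interpretations are emitted by the fit object
(γ is the one used downstream). Nonpositive counts are dropped with a
warning; a nonpositive rate yields τ = NA with a flag rather than an
error. `normalize_to_control()` gives fold-changes (γ̃, α̃) and the
imbalance `log2(γ̃/α̃)`: 0 on the proportionality line, negative for
growth-limited conditions, positive for division-limited ones, and
antisymmetric under swapping equal-magnitude growth and division
perturbations. "Cell size" from the screen is the per-condition median
of the per-cell segmented area (`per_drug_cell_size()`), configurable
in principle to nuclear area; `size_state_correlation()` correlates it
with PC1.

# Cohort similarity

`cohort_correlations()` computes a cohort's protein–protein Pearson
matrix only when the cohort has strictly more than 30 samples (the
floor is exclusive). `similarity_to_reference()` deletes the trivial
diagonal from both matrices, aligns panels by protein name, and
correlates each cohort row with the corresponding reference row
(pairwise-complete, ≥ 4 shared finite entries — with the default
8-protein panel each row has 7); the overall score is the mean over
proteins. Including the diagonal would inflate similarity, which the
tests guard against by construction. The reference correlation matrix
is a user input: which timepoint and drug set define the screen-side
reference is an analysis decision, not hard-coded.
`enrichment_strength()` is the scalar `log10(observed/expected)`, with
observed = 0 reported as NA rather than −Inf.

# Problem sizes, tolerances and reproducibility

The test suite and the acceptance script run the full pipeline at these
sizes, chosen as the smallest scales at which each property is
meaningfully exercised: barcode calling on 12 clones × 300 cells
(640 × 640 px fields, ~60 fields); the screen at 100 drugs × 12
reporters × 5 timepoints × ~200 cells per clone per well (~4 million
cells); 1000 random sample pairs for the KS oracle at 1e-12; 20 random
5 × 4 problems for the ridge oracle at 1e-6; cohorts of 10^4 samples
for similarity convergence. Exactness claims (noiseless growth
round-trip, phi identities) are asserted at 1e-10–1e-12; Monte-Carlo
claims use tolerances derived from their sampling SE (e.g. ±0.02 for a
correlation at n = 10^4, Fisher-z SE ≈ 0.01).

Every stochastic step takes a seed and fans it out to child seeds, so
two runs with the same configuration are identical file-for-file
(`run_pipeline()` writes a manifest recording seed, versions and stage
toggles). All artifacts are plain CSV/JSON/TIFF.

# Known limitations

* Synthetic readout distributions and image geometry are plausible
  stand-ins, not fits to any real cell line; recovery results validate
  the estimators, not the biology.
* The KS score saturates at ±1, compressing strong effects; the
  active-drug fraction on the synthetic screen reflects the planted
  effect sizes, not any empirical hit rate.
* Barcode confidences from tree ensembles are overconfident away from
  class boundaries; out-of-panel detection by confidence alone is
  heuristic.
* The adherence metric is reported in its printed, scale-dependent
  form by default; cross-dataset comparisons should use the normalized
  variant deliberately.
* Cohort similarity assumes the protein panel is a faithful surrogate
  for pathway activity and that a single reference correlation matrix
  is meaningful across cohorts.
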