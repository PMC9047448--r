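---
title: "Cell typing from single-cell MALDI-MSI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell typing from single-cell MALDI-MSI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msicelltyper)
```

## The problem

Breast-cancer cell lines carry receptor-status-linked lipid profiles:
the same lipid species appear in every line, but in line-specific
ratios. MALDI-MSI at 5 µm pixels resolves individual cultured cells
(20–150 µm diameter), so a cell's pixels can be averaged into one
spectral fingerprint, and a labeled collection of fingerprints can
train a classifier that recognizes cell lines — or the three clinical
receptor subtypes (triple negative, HER2+, ER+PR+) — directly in
tissue images acquired at histology resolution (30 µm pixels), with no
staining. `msicelltyper` implements this pipeline: preprocessing,
library construction, PCA/LDA recognition with outlier rejection,
cross-validated evaluation, pixel-wise tissue mapping (batch and
streaming), and cross-instrument ratio comparison.

## Preprocessing

Spectra are centroided peak lists. Three fixed steps turn one into a
feature vector:

1. **rms normalization** — intensities divided by their root mean
   square, computed over the detected centroids (not a resampled
   profile). This removes per-pixel response differences; any positive
   rescaling of a spectrum normalizes to the same vector.
2. **Mass-range restriction and binning** — centroids with
   600 ≤ m/z < 950 are summed into half-open 0.2 Da bins anchored at
   600 (1750 bins). Summing conserves the in-range ion count; the
   half-open convention makes edge assignment deterministic (a centroid
   at exactly 600.0 lands in bin 1; 950.0 is dropped). Bin indices are
   corrected after the floor division so floating-point edges
   (600.2, 600.4, …) never land one bin off.
3. **ROI mean** — a cell's fingerprint is the element-wise mean of its
   pixels' normalized, binned vectors. The order is fixed:
   normalize, then bin, then average, and the mean is *not*
   re-normalized afterwards. The alternative (average raw spectra, then
   normalize) weights bright pixels more; with per-pixel normalization
   every pixel of a cell contributes equally. The choice is
   regression-tested so cross-implementation comparisons are exact.

## The recognition model

For a library `X` (cells × 1750 bins) with class labels:

- **PCA** on mean-centered rows keeps the smallest component count
  whose cumulative explained variance reaches `variance_kept`
  (default 0.95, capped at `n − 1`). A variance criterion, rather than
  a fixed component count, keeps the reduction reproducible across
  library sizes.
- **Fisher LDA** in PCA space: with pooled within-class covariance
  `Sw` (ridge-loaded only if numerically singular) and between-class
  scatter `Sb`, the discriminants solve `Sb a = λ Sw a`, computed via
  symmetric whitening (`Sw^{-1/2} Sb Sw^{-1/2}`), keeping
  `min(C − 1, k)` directions. Each direction is scaled to unit pooled
  within-class variance and sign-canonicalized (largest-magnitude
  loading positive), so distances in discriminant space are in
  within-class standard-deviation units and projections are
  reproducible to the sign.
- **Classification** is nearest class centroid by Euclidean distance in
  discriminant space; ties break lexicographically by class label.

### The outlier rule

Each class stores a scalar dispersion `s_c`; a spectrum whose winning
distance exceeds `outlier_multiplier × s_c` (default multiplier 3) is
returned as `OUTLIER` instead of a class. Force mode disables this —
the behavior of recognition systems that assign every pixel
regardless, which is exactly what makes necrotic tissue show up as
spurious classes.

Two readings of "standard deviation" are implemented
(`dispersion_type`):

- `"rms_distance"` (default): `s_c` is the RMS distance of the class's
  training points to their centroid. The rule then bounds the full
  discriminant-space distance, and with `d` directions a same-class
  spectrum (distance concentrated near `s_c`) is flagged only in the
  far tail — a few percent of spectra, matching the observed behavior
  of deployed models whose including-outliers rates are only a few
  points below their excluding-outliers rates.
- `"per_direction"`: the root of the mean per-direction variance about
  the centroid, i.e. `s_c ≈ s_rms / √d`. With `d = 13` directions
  (14 classes) a typical same-class distance is `√d ≈ 3.6` of these
  units, so the ×3 rule would flag most correct spectra — useful as a
  strict novelty filter, but not as the operating point of the
  pipeline. It is provided because the deployed systems do not document
  their reading.

A class whose training points are numerically identical gets a tiny
positive dispersion floor so the rule stays well-defined in the
noiseless limit.

### Evaluation

- `crossval()`: stratified fivefold CV (every fold holds a
  representative share of every class, assignment seeded), fitting on
  four folds and classifying the fifth in outlier mode. Reported
  rates: **excluding outliers** (correct / non-outlier predictions) and
  **including outliers** (correct / all, outliers counted wrong); the
  former is always ≥ the latter.
- `holdout_validate()`: per-class split at `round(2/3 · n_c)` training
  cells (minimum 2), validation classified in outlier mode.

The outlier rule is applied at prediction only; training spectra are
never trimmed.

## The synthetic generator

The generator exists so every downstream stage has ground truth. It
emulates the study conditions, not the physics:

- **Panel**: 79 lipid species on homologous-series masses across m/z
  600–950, anchored at PC 34:1 (760.585) and PC 36:1 (788.616).
- **Profiles** (`make_profiles`): one shared Dirichlet-drawn base
  abundance vector; each class multiplies it by
  `exp(separation × (subtype component + line component))`, both sparse
  Gaussian log-perturbations (≈10% and 15% of the panel), then
  renormalizes. Classes therefore differ in ratios of the same lipids,
  never in presence/absence. The subtype-shared component gives the
  round-robin receptor labels real signal — the biological premise is
  that lipid patterns track receptor status, so lines of one subtype
  should be closer to each other than to other subtypes. `separation =
  0` collapses all classes onto the base profile; 1.0 is the default
  operating point.
- **Spectra** (`synth_spectrum`): one centroid per panel lipid,
  intensity = scale × abundance × lognormal noise with CV `noise_cv`
  (default 0.05 — the study reports no within-culture variance, so
  this is a modeling choice: tight enough for the high-90s
  classification regime, far from separability-by-accident), plus ~10
  uniformly placed background centroids at ≤0.02% of the signal scale,
  kept ≥0.05 Da away from panel masses.
- **Cell images** (`synth_cell_image`): non-overlapping disks, diameter
  uniform in 20–150 µm on a 5 µm grid; a pixel belongs to a cell when
  its center falls inside the disk. Any disk of diameter ≥ 20 µm then
  covers ≥ 4 pixels (worst-case center placement leaves the four
  nearest pixel centers within 0.71 pixels, radius is 2). Placement is
  rejection sampling with bounded retries; failure reports how many
  cells fit.
- **Tissue images** (`synth_tissue_image`): an elliptical tumor of the
  main profile at 30 µm pixels, a contiguous necrotic subregion grown
  by breadth-first search to the requested fraction of tumor pixels,
  and an unmeasured background border (acquisitions measure the
  sectioned area; `measure_background = TRUE` overrides). Necrotic
  spectra are the main profile mixed 50/50 with a uniform profile at
  10% intensity — dim and ratio-distorted, so they sit far from every
  class centroid and exercise the outlier rule the way necrosis does.

Every generator is a pure function of its arguments including the seed,
and leaves the caller's RNG stream untouched.

**What the generator does not emulate** — isotope envelopes, ion
mobility, mass-calibration drift, matrix clusters, cell-shape
irregularity, intra-cell compartment structure, spatial intensity
gradients, or realistic necrosis chemistry. Passing tests therefore
demonstrate that the pipeline recovers the structure this data model
encodes (ratio-coded classes under multiplicative noise); they do not
certify performance on instrument data.

## Numerical and design choices

- Coordinates are 0-based (row, col) row-major; imzML's 1-based x/y map
  as `x = col + 1`, `y = row + 1`. Only processed (centroided) imzML is
  supported; continuous mode is refused with advice to centroid first.
- Writers are atomic (temp file + rename); model files are versioned
  plain text with `%.17g` numbers, so doubles round-trip bitwise and a
  truncated file is always detected.
- "Highest-intensity cells" is operationalized as total ion count over
  the ROI's raw spectra — the simplest monotone brightness criterion;
  ties break by cell id. Overlapping ROIs are tolerated (with a
  warning) at the file-reading stage but rejected at library
  construction, where a shared pixel would double-count evidence.
- One-way ANOVA mean squares are accumulated directly (not via a model
  fit) so the degenerate case — zero within-group variance with
  non-zero between-group variance — can be flagged as `F = +Inf`
  rather than an error. Per-lipid verdicts are compared against a
  single critical value with no multiplicity correction, mirroring
  how such comparisons are reported; a Bonferroni option exists but is
  off by default.
- Under the no-instrument-effect null, the expected significant-lipid
  fraction equals α, but single datasets scatter widely because every
  lipid's ratios share the reference peak's noise; the property is
  therefore asserted on the mean over many generator seeds.

## Problem sizes

The shipped tests and the acceptance script run a 14-class × 16-cell
library (224 spectra × 1750 bins, fivefold CV at both label levels in
under a second), a 70-cell 5 µm image (~64k pixels), and a 64×64
tissue image — sizes chosen to exercise every code path at a few
seconds per case while matching the study's corpus scale (229 cells,
14 lines).

## Known limitations

- The discriminant model assumes classes are unimodal blobs sharing a
  within-class covariance; strongly multimodal classes (e.g. mixed
  morphologies within one line) would need a different classifier.
- The subtype model inherits its geometry from the line-level
  structure; with subtype-incoherent lines its nearest-centroid
  assignment degrades.
- No peak picking, deisotoping, or mass recalibration: inputs must be
  centroided and mass-aligned to within the bin width.
- Streaming classification is stateless per spot by design (labels
  provably equal batch results); it does not model acquisition-time
  drift corrections.
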