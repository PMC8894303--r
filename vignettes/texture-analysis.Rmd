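---
title: "Pleural-line texture analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pleural-line texture analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleuratex)
```

## The model

Lung ultrasound B-mode frames of the pleural line are analysed as 8-bit
greyscale images (intensities 0–255). The unit of texture information is the
grey-level co-occurrence matrix (GLCM): after uniform quantization of the
fixed 0–255 range into `Ng` levels, `P(i, j; d, θ)` is the probability of
finding level `i` at displacement distance `d` and direction `θ` from level
`j`, estimated over every ordered pixel pair whose two pixels both fall
inside the region of interest (ROI). Counts are accumulated symmetrically
(each pair increments both `(i, j)` and `(j, i)`), which makes `θ` and
`θ + 180°` equivalent and the matrix exactly symmetric, and are normalized by
the realized pair count — not a nominal one, because polygonal ROIs
following the pleural line are irregular and border effects matter.

Twelve scalar features summarize each matrix (see `?compute_features` for the
formulas): contrast, cluster shade, cluster prominence, entropy, variance,
mean, correlation, energy, homogeneity, and the mean, entropy and variance of
the level-sum distribution `p_{x+y}`. Verbal descriptions of these features
map onto the classical second-order statistics literature ("angular second
moment" for energy, "inverse difference moment" for homogeneity), so the
formulas are fixed to the canonical Haralick/Conners conventions. Cluster
shade is the diagnostically interesting third moment: positive when bright
clusters sit on a darker background (normal pleura), negative when darker
regions sit on a lighter background (edematous pleura).

Per frame, one GLCM is computed per `(d, θ)` combination, features are
computed per matrix, and the feature values are averaged across all
combinations. An alternative "matrix" mode averages the four directional
matrices per distance into a direction-invariant matrix before computing
features, then averages over distances; both reductions are exposed via
`glcm_config(averaging = )` because published workflows describe both, and
the feature-wise average is the default as the more specific description of
the per-frame value. Frames map to the 12 standard chest zones (anterior,
lateral, posterior × upper, lower × left, right); the subject-level value is
the arithmetic mean over available zones (`n_zones` is recorded; a complete
examination has 12).

## Parameters and defaults

* `n_levels` (Ng), default **16**: balances computation time against
  preservation of image information; values up to 64 change little.
  Quantization is uniform over the fixed 0–255 range rather than per-image
  min–max, so level units are comparable across images and subjects —
  per-image rescaling would destroy cross-subject comparability of the mean
  and sum-mean features.
* `distances`, default **1–4** pixels: short displacements that resolve
  fine pleural detail. Whether a clinical analysis should average over 1–4 or
  fix a single distance is not settled; the default averages, and a single
  value can be configured.
* `angles`, default **0°, 45°, 90°, 135°**: the four nearest-neighbour
  directions; with symmetric accumulation they exhaust the 8-neighbourhood.
  Offsets are 0-based `(row, col)` with rows increasing downward:
  0°→(0,d), 45°→(−d,d), 90°→(−d,0), 135°→(−d,−d). The sign convention is
  observationally irrelevant after symmetrization, but note that libraries
  measuring angles with the +row axis pointing down swap the two diagonal
  labels.
* Entropies are reported in **bits** (base-2 logarithm); any fixed base only
  rescales, base 2 is declared for reproducibility.
* `variance_sum` is the dispersion of the level-sum distribution about
  `mean_sum` (a typo lineage in early texture literature instead centres it
  on the sum entropy; the histogram-dispersion reading is used here).

## Degenerate inputs and numerical choices

* A constant ROI has `σx = 0`; correlation is then **undefined** and recorded
  as `NA`, not coerced to 0 or 1, and excluded from frame- and zone-level
  correlation averages only. A constant ROI carries no linear-dependence
  information, and coercion would bias group means.
* An ROI through which no displaced pixel pair fits raises an error rather
  than returning an empty matrix.
* Rectangle masks take the closed interval between the two corners; polygon
  masks use the even–odd rule at pixel centers with boundary pixels counted
  inside — the simplest fully testable convention. Coordinates are 0-based
  `(row, col)` throughout.
* ROC cut-offs are midpoints between adjacent distinct scores; ties on
  Youden's J are broken toward higher sensitivity. Both rules are
  determinism conventions, not claims about optimality.
* The bootstrap AUC comparison resamples within class (stratified), keeping
  both groups present in every replicate even at the 8-versus-16 scale; a
  two-sided p-value is read from the normal approximation to the bootstrap
  distribution of the AUC difference.
* The cross-validated error uses the single-feature Youden rule as the
  classifier — per-feature accuracy is the quantity of interest and no other
  classifier is implied — with stratified folds and a seeded assignment.
* Inter-observer agreement is ICC(2,1): two-way random effects, absolute
  agreement, single measure, the natural reading of "two-way models for
  agreement" with two observers; Cronbach's α accompanies it.

## What the synthetic module emulates

Patient images are not redistributable, so two generators make every stage
testable:

* **Phantoms** (`generate_phantom`) emulate the qualitative appearance of the
  three pleural-line classes: bright discs on a darker speckled background
  (healthy), dark discs on a lighter background (CPE), and large connected
  uniform dark-grey patches from a thresholded smoothed random field (ARDS).
  Speckle is a multiplicative unit-mean Rayleigh-like factor, the minimal
  ultrasound speckle surrogate. Default levels (healthy 140/235, CPE 185/90,
  ARDS 170/85 on the 0–255 scale), 10% blob coverage with radius 3 px, an
  8 px smoothing scale and 0.3 speckle weight were chosen once as a
  plausible rendering of those descriptions. Only *sign and ordering* claims
  are asserted on phantoms — healthy cluster shade positive, CPE negative,
  ARDS correlation above CPE — never feature magnitudes: the phantoms are
  not beam-physics simulations (no PSF convolution, attenuation or scan
  conversion), so passing tests show the features respond to the intended
  texture structure, not that the generator reproduces clinical images.
* **Feature cohorts** (`simulate_group_features`) draw per-subject feature
  values from independent Gaussians with the published per-group means and
  SDs (ARDS n = 8, CPE n = 16), the minimal generative model consistent with
  reported summary statistics. Draws outside a feature's theoretical range
  (correlation above 1, negative energy) are clipped and the clipped
  fraction reported. For two Gaussian groups the population AUC is the
  binormal closed form Φ(|μ₁−μ₂|/√(σ₁²+σ₂²)), so large simulated cohorts
  recover the published AUROC of a feature exactly when that AUROC is
  consistent with the group summary statistics (contrast, cluster shade,
  entropy, homogeneity, entropy sum). For the remaining features the
  published AUROC reflects the particular 24-subject sample rather than the
  summary statistics — a published correlation AUROC of 1.000 is not
  recoverable from overlapping Gaussians — and no attempt is made to
  reproduce those.

## Problem sizes used in validation

The test suite validates the GLCM engine against a brute-force
pair-enumeration oracle on 200 random frames up to 32×32 pixels with random
masks, and against an independent GLCM routine on unmasked frames; feature
formulas against a naive triple-loop evaluator and a grey-level reflection
symmetry on random matrices; AUROC recovery on 10⁵ subjects per group;
phantom semantics over 100 seeded replicates per class; and the ROC layer
against the Mann–Whitney identity on 100 random datasets plus a 2000-sample
permuted-label null. These sizes give comfortable Monte-Carlo margins for
every asserted tolerance while keeping the suite quick.

## Known limitations

* Frame choice within a clip, ROI placement, and the "most pathological
  area" selection are operator inputs, not algorithms; the package neither
  detects the pleural line nor scores B-lines.
* Only single still frames are analysed per zone (multi-frame averaging
  within a zone exists as an option but defaults off, matching the
  single-frame design of the underlying workflow).
* The DICOM reader supports the uncompressed little-endian transfer
  syntaxes and 8-bit depth used by B-mode grey-scale exports; compressed or
  >8-bit data are rejected explicitly. Vendor overlays are not stripped —
  excluding them is the ROI's job.
* Zone-level feature variance is unknown; the simulator targets
  subject-level distributions only, so simulated cohorts cannot validate
  the zone-to-subject aggregation variance, only its mean behaviour.
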