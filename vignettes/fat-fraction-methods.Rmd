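---
title: "Quantitative rotator cuff fat-fraction analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative rotator cuff fat-fraction analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuffquant)
```

## Scope and data model

`cuffquant` analyses fatty infiltration of the four rotator cuff
muscles (SSP, ISP, SSC, TM) from three co-registered, axis-aligned 3D
grids: a T1-like intensity volume, a quantitative fat-fraction (FF)
volume, and an integer segmentation mask that also labels the scapula
and humerus. FF is always carried on the 0–100 percent scale; values
on the 0–1 scale are rejected rather than silently rescaled, because a
genuine 0.5 % fat voxel is indistinguishable from a mis-scaled 50 %
one after the fact.

Two conventions matter everywhere downstream:

* **Muscle membership comes from the mask, never from the values.** A
  muscle voxel with 0 % fat counts in every mean. The common packaging
  step of zeroing all voxels outside the muscles (`mask_to_muscle()`)
  is display/preparation only, and is idempotent.
* **Indices are 1-based**, as everywhere in R's imaging stack; slices
  are full 2D planes orthogonal to the declared `slice_axis`. Axis
  reversal maps slice `i` to `n + 1 - i`.

Grids must be pre-registered. The NIfTI reader accepts only
orientation matrices that are signed axis permutations (tolerance
`1e-3`), because resampling oblique acquisitions is a registration
problem this package deliberately does not solve.

## Five-class quantization and reconstruction

Voxel-wise FF is discretized into five classes at boundaries 15, 30,
45 and 60 %. The intervals are lower-inclusive and half-open:
`[0,15) [15,30) [30,45) [45,60) [60,100]`. On continuous-valued data
the boundary convention is measure-zero; it is fixed (and tested
exhaustively on a 0.01-step grid) purely for determinism.

Reconstruction maps class *k* to a representative FF: the interval
midpoints 7.5 / 22.5 / 37.5 / 52.5 for classes 0–3 and 80 for the
open-ended top class (the midpoint of [60,100]). No single
reconstruction is canonical for an open-ended class; the
representatives are therefore an explicit field of `class_scheme()`,
so cohort-empirical class means can be swapped in without touching any
downstream code. With the defaults the round trip
`dequantize(quantize(x))` is within 7.5 points of `x` below 60 % fat
and within 20 points above — the bound that propagates through every
class-derived muscle mean.

## Whole-muscle measures

Three measures are computed per muscle, all as unweighted voxel means
(the grid is uniform, so voxel counts are the correct weights):

* `whole_muscle_ff()` — the mean of the quantitative FF values; the
  reference.
* `class_derived_ff()` — the mean of per-voxel class representatives;
  what a class-mask predictor can deliver.
* `binary_ff()` — the classical baseline: voxels with FF *strictly*
  above 40 % count as 100 % fat, all others as 0 %. Strictness matters
  on synthetic data, where exactly-at-threshold voxels exist and must
  fall on the muscle side.

The binary measure discards all sub-threshold fat, so on muscles whose
voxels all sit below 40 % it reads exactly 0 while the true mean does
not — a structural underestimation, not a sampling artefact. The test
suite reproduces this on a 24-phantom cohort and shows the Wilcoxon
signed-rank comparison of absolute errors rejecting at far below
α = 0.001.

## Y-slice detection

The Y-slice — the conventional grading location, where the scapular
spine merges with the scapular body — is found in two steps:

1. **Lateral direction**: the sign of (humerus centroid − scapula
   centroid) along the slice axis; the humerus side is lateral.
2. **Connectivity transition**: iterating from the lateral end,
   skipping slices without scapula, the first slice whose scapula
   cross-section forms exactly one 2D connected component.

In-plane connectivity is 8-connected by default (configurable to 4):
anisotropic acquisition and mask transfer can open single-voxel
diagonal gaps that 4-connectivity would misread as fragmentation.
Slices with no scapula are skipped rather than counted as "one
component of size zero". The rule fires verbatim even when the first
single component is a tiny fragment (for example a lone acromion tip);
such detections are flagged (`small_component`) when the component
area is below 50 mm², mirroring the manual verification this step gets
in practice, rather than silently second-guessed.

## Slice profiles and cohort aggregation

For each muscle, every slice gets its mask area (voxel count ×
in-plane pixel area), the mean FF over its muscle voxels, and the
signed lateral distance `(slice − y_slice) × slice_spacing ×
lateral_direction` (positive lateral, negative medial). Distances are
computed from slice indices times the stored slice spacing, i.e. the
inter-slice gap is taken equal to the slice thickness. Only slices
with area strictly greater than 50 mm² are `included`; a slice at
exactly 50 mm² is excluded.

An exact conservation law ties the profile to the whole-muscle
measure: the area-weighted mean of the *unfiltered* slice means equals
`whole_muscle_ff()` to 1e-9. The tests enforce it on every phantom.

Included slices are linearly interpolated onto a uniform 5-mm grid
anchored at 0 (the Y-slice), with no extrapolation beyond the included
extent; anchoring at the Y-slice rather than at the most lateral slice
makes positions comparable across cases. Cohort curves report the
across-case sample mean and SD (n−1 denominator) at each grid
position, and only at positions covered by at least `min_n = 20`
cases — positions supported by fewer cases are dropped entirely rather
than shown with unstable dispersion.

### Cross-grid interpolation

`coronal_to_sagittal()` brings a second acquisition of the same
subject onto the sagittal grid: masks by nearest neighbour, FF by
*normalized masked* linear interpolation — `FF · 1{muscle}` and
`1{muscle}` are each trilinearly interpolated and divided. Plain
trilinear interpolation of the zero-outside-muscle FF field would
dilute every boundary voxel with background zeros and bias
small-muscle means down by around 10 %; normalizing by the
interpolated support removes that bias while remaining linear
interpolation of FF over its support. T1 intensity, which has no
masked-field semantics, is interpolated plainly.

The dual-rendering test (one analytic phantom rasterized natively at
two resolutions, resampled, and compared) is run on streak-free
phantoms: 2-mm fatty streaks rasterize differently at different grid
resolutions, so with streaks the two renderings genuinely differ —
the same sagittal/coronal discrepancy seen in clinical data when the
low-resolution direction changes. On smooth fields the whole-muscle
FF agrees within 2 % after resampling.

## The phantom generator

The phantom is a continuous analytic model — all random parameters are
drawn once, seeded, in an order and count independent of the severity
values — rasterized onto any grid of matching physical extent. That
design is what makes native dual-resolution renderings possible, and
it guarantees two properties the tests rely on:

* **determinism** under a fixed seed, and
* **monotonicity**: raising one muscle's severity never lowers that
  muscle's true whole-volume FF, because the base level is affine in
  severity, streaks are applied with `pmax`, and a higher severity
  activates a superset of the same candidate streaks.

Geometry (fixed, in fractional coordinates): four disjoint tapered
ellipsoid muscles whose in-slice area exceeds the 50 mm² filter over
roughly 80 % of their slice extent and falls below it at the tips
(so the filter is actually exercised); a scapula drawn as two disjoint
bars on every slice strictly lateral of the planted `y_slice_true` and
as one merged bar from there medially; a humerus box at the lateral
end. Grids too coarse to rasterize the two-bar/gap structure are
rejected as geometrically infeasible rather than silently producing a
phantom that violates its own connectivity contract.

Signal model: FF = clip(base + smooth, 0, 100) overlaid with
high-fat streaks (70–95 %), where base = 5 + 55 · severity and
*smooth* is a sum of two low-frequency sinusoids (±8 points). T1 is a
monotone piecewise-linear map of FF (100 + 2·FF in muscle, plateaus in
bone and background), multiplied by a linear coil-falloff field that
retains a fraction `falloff` (default 0.3, matching a roughly 70 %
signal loss across the field of view) at the far edge, plus additive
Gaussian noise (SD 5 on a ~100–300 intensity scale). Optional
contrast-agent lesions force FF below 15 % while setting T1 to the
95th percentile of muscle intensity — the confound that makes
contrast agent mimic fat on T1.

Defaults: 16 × 32 × 32 voxels at 3.5 × 1 × 1 mm. The 3.5-mm slice
thickness matches clinical sagittal shoulder MRI; the 1-mm in-plane
spacing is a phantom-scale choice — at the clinical 0.31 mm a desk-
sized grid could not hold four muscles each above the 50 mm² filter —
and the metric/IO layers handle clinical spacings unchanged. Default
severities (SSP 0.20, ISP 0.15, SSC 0.18, TM 0.12) put whole-muscle FF
near 12–16 %, the range reported for mildly to moderately infiltrated
cohorts; `generate_cohort()` draws severities over [0,1] by default so
all five classes occur across a cohort.

What the phantom does *not* emulate: realistic scapular anatomy, MR
physics (noise is Gaussian, not Rician), partial-volume mixing at
muscle borders, and inter-modality registration error. Passing tests
therefore validate the measurement, detection and evaluation
machinery — not clinical prediction accuracy on patient data.

## Predictors

The predictor contract (`predict()` on an `ff_predictor`) produces a
class mask on the muscle voxels, sentinel −1 elsewhere. Three
reference implementations:

* **oracle** — quantizes the case's own ground-truth FF; the only kind
  allowed to read FF at predict time. It pins down the evaluation
  chain: oracle predictions make the class-derived path agree exactly
  with ground-truth quantization.
* **calibrated_threshold** — cut-points on T1 z-scored within the
  muscle mask. Total per-voxel agreement decomposes into one term per
  boundary, so each cut-point is optimized exactly by a sorted scan;
  the cut-points are then sorted to enforce monotonicity. On
  falloff-free noise-free phantoms the monotone T1–FF map makes it
  exact (accuracy 1); with coil falloff intensity alone is
  non-identifiable and its accuracy drops — the designed failure mode.
* **mini_cnn** — a patch-wise convolutional classifier: a single
  hidden-layer softmax network (via `nnet`) over each voxel's 3×3×3
  z-scored intensity patch plus its three normalized coordinates,
  applied convolutionally over the volume at predict time. The spatial
  inputs let it compensate the position-dependent falloff that defeats
  thresholding. Training subsamples up to 3000 muscle voxels per case;
  seed fixes both the subsample and the initial weights, making
  training bit-reproducible. On 8 training / 4 held-out phantoms its
  whole-muscle mean absolute error (~7 points) is well under the
  binary baseline's (~20–29 points) for every tested seed — the claim
  is about the pipeline and evaluation machinery at phantom scale, not
  about clinical-grade accuracy.

## Evaluation statistics

Signed errors are predicted − ground truth; summaries use the sample
SD (n−1). The paired comparison of two methods' absolute errors uses
the Wilcoxon signed-rank test with the classic conventions: zero
differences dropped, midranks for ties, statistic W⁺ = sum of ranks of
positive differences. For n ≤ 25 effective pairs the exact null is
computed by generating-function convolution over the doubled midranks
(exact even under ties, where the textbook tables do not apply); for
larger n, the normal approximation with continuity correction and
tie-corrected variance. The tests verify exact agreement with full
2ⁿ sign-pattern enumeration for all n ≤ 12 and a type-I error within
[0.03, 0.07] at nominal α = 0.05 over 1000 null simulations.

Per-class errors stratify slice-wise errors by ground-truth class: for
each slice and class, the error between predicted and ground-truth
mean FF over that class's muscle voxels in the slice; classes are then
summarised across slices (absent classes reported explicitly empty).

Goutallier tallies (`gg_tally()`) are cohort summaries of expert
grades, which are clinical inputs here; `rc_cohort_grades()` ships the
published 99-patient (396-muscle) grade table for the worked example:
116 / 175 / 86 / 8 / 11 muscles at grades 0–4, with 4.8 % at grade 3
or 4.

## Problem sizes and numerical choices

The test suite and acceptance script run on 16 × 32 × 32 phantoms:
oracle-equivalence and Y-slice checks on 100 phantoms each, cohort
analyses on 24 (the evaluation-cohort size), predictor training on 8
with 4 held out. Oracle comparisons are asserted to 1e-9 (means in
double precision), exact-test agreement to 1e-12, NIfTI scalar round
trips to 1e-6 (single-precision storage), spacing comparisons to
1e-3 mm. Empty muscles, all-tied comparisons, always-fragmented
scapulae and infeasible rasterizations are explicit errors, not silent
results.
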