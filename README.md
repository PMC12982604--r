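# cuffquant

Quantitative, voxel-wise fat-fraction analysis of the rotator cuff
muscles from co-registered MRI volumes.

## The problem

Fatty infiltration of the four rotator cuff muscles — supraspinatus
(SSP), infraspinatus (ISP), subscapularis (SSC) and teres minor (TM) —
is a primary prognostic factor for rotator cuff repair. Clinical
grading (the 5-level Goutallier grade) is read visually from a single
sagittal slice at the *Y-view* and is highly observer-dependent, while
binary fat/muscle separations on T1-weighted MRI discard every voxel's
sub-threshold fat content and therefore systematically underestimate
the muscle's true fat fraction.

`cuffquant` implements the quantitative alternative: given a
T1-weighted-like intensity volume, a Dixon-derived fat-fraction (FF)
volume on the 0–100 % scale, and an integer segmentation mask (4
muscles + scapula + humerus), it provides

- **five-class FF quantization** and its quantitative reconstruction:
  voxel classes `[0,15) [15,30) [30,45) [45,60) [60,100]` % with class
  representatives `7.5 / 22.5 / 37.5 / 52.5 / 80` %, so that a
  (predicted or ground-truth) class mask maps back to a quantitative
  volume;
- **whole-muscle FF metrics**: the quantitative voxel mean, the
  class-derived mean, and the binary baseline
  `100 · #{FF > 40 %} / #muscle voxels` (fat voxels counted as 100 %
  fat, the rest as 0 %);
- **automatic Y-slice detection** from the bone masks: lateral
  direction from the humerus-vs-scapula centroid, then the first slice
  (from lateral to medial) whose scapula cross-section is a single 2D
  connected component;
- **slice-wise FF distribution profiles** along the frontal axis:
  per-slice muscle means with a strict 50 mm² area filter, signed
  lateral distance to the Y-slice, linear resampling to a 5-mm grid
  anchored at the Y-slice, and cohort mean ± SD curves at positions
  covered by ≥ 20 cases;
- **pluggable voxel-wise class predictors** (ground-truth oracle,
  calibrated intensity thresholds, and a small patch-wise
  convolutional network) standing in for a full-scale segmentation
  network, plus **method-comparison statistics** (signed error
  summaries and an exact Wilcoxon signed-rank test on paired absolute
  errors);
- a **synthetic shoulder phantom generator** with known ground truth
  (per-muscle severity, fatty streaks, coil-distance signal falloff,
  contrast-agent lesions, and a scapula whose per-slice connectivity
  transitions at a planted Y-slice), so the whole pipeline is testable
  without patient data.

Volumes are read and written as NIfTI (`.nii` / `.nii.gz`) via RNifti;
all tabular results are tibbles that chain with the usual dplyr verbs,
and result types have `autoplot()` methods.

## Worked example

```r
library(cuffquant)

# a phantom with a heavily infiltrated supraspinatus
ph <- generate_phantom(phantom_spec(
  severity = c(SSP = 0.6, ISP = 0.2, SSC = 0.35, TM = 0.1), seed = 42))

measure_case(ph$case)
#>    case_id muscle method        mean_ff voxel_count
#>  1 phantom SSP    quantitative    43.5          876
#>  2 phantom ISP    quantitative    19.8          833
#>  3 phantom SSC    quantitative    29.1          932
#>  4 phantom TM     quantitative    13.4          822
#>  5 phantom SSP    binary          40.6          876
#>  6 phantom ISP    binary           5.64         833
#>  7 phantom SSC    binary           7.40         932
#>  8 phantom TM     binary           3.41         822
#>  9 phantom SSP    class_derived   43.4          876
#> 10 phantom ISP    class_derived   19.5          833
#> 11 phantom SSC    class_derived   28.4          932
#> 12 phantom TM     class_derived   10.5          822
```

The quantitative column is the reference: the mean FF over each
muscle's voxels. The class-derived measure (quantize, then average the
class representatives) tracks it within ~1–3 points, while the binary
measure collapses ISP from 19.8 % to 5.6 % and TM from 13.4 % to
3.4 % — the structural underestimation that motivates voxel-wise
quantification.

```r
detect_y_slice(ph$case$mask)
#> <y_slice_result> slice 8, lateral direction +1, area 100 mm^2
```

An end-to-end cohort run with the ground-truth-oracle predictor:

```r
res <- run_pipeline(run_config(n_cases = 24, seed = 1))
res$errors_class       # class-derived vs quantitative, per muscle
#>   muscle     n mean_error sd_error mean_abs_error
#> 1 ISP       24    -0.0403    1.08           0.929
#> 2 SSC       24    -0.333     0.963          0.831
#> 3 SSP       24     0.245     1.42           1.09
#> 4 TM        24    -0.0381    1.71           1.18
res$comparison         # class-derived vs binary absolute errors
#> Wilcoxon signed-rank comparison of paired absolute errors
#>   W+ = 0, n = 96 (0 zero pairs dropped)
#>   two-sided p = 1.81e-17 (normal approximation with continuity correction)
```

Class-derived errors stay near zero (mean absolute error ~1 point)
while the binary baseline's absolute errors average ~25 points on the
same cohort; the signed-rank test rejects their equality decisively.
`autoplot(res$cohort_profile)` draws the cohort mean ± SD FF curves
against lateral distance to the Y-slice.

A thin command-line wrapper over the same functions is installed at
`inst/cli/cuffquant.R`
(`Rscript cuffquant.R simulate|quantize|measure|yslice|profile|cohort|run …`).

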