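# aslpattern

Multi-class pattern recognition for arterial spin labeling (ASL) perfusion
maps.

Pharmacological MRI studies often ask whether two drugs change resting brain
physiology in distinguishable ways. Pulsed-continuous ASL (pCASL) measures
regional cerebral blood flow (rCBF, ml/100 g/min) quantitatively and
non-invasively, and a multivariate classifier trained on whole-brain flow
patterns can discriminate drug conditions subject-by-subject where
voxel-at-a-time testing lacks sensitivity. `aslpattern` implements that
analysis end to end for researchers working with co-registered perfusion
data (or validating methodology on synthetic data):

- **CBF quantification** from control/label signal pairs with a coil
  sensitivity map \(C\):
  \(\mathrm{CBF} = \rho_b (S_c - S_l) \,/\, [\,2 \alpha C \omega_a T_{1a}
  e^{-\delta/T_{1a}} (1 - e^{-t_l/T_{1a}})\,]\),
  reported in ml/100 g/min, plus the neighborhood-maximum
  inversion-recovery sensitivity calibration.
- **Preprocessing** into classifier features: Gaussian smoothing (FWHM in
  mm), averaging of the first *k* scans, within-subject mean-centering, and
  vectorization over an analysis mask.
- **Sparse multinomial logistic regression (SMLR)** with an elastic-net
  penalty, \(J(w) = L(w) - \lambda_1\lVert w\rVert_1 -
  \lambda_2\lVert w\rVert_2^2\), trained by a component-wise soft-threshold
  ascent (C++ core) that produces exact zeros and a provably non-decreasing
  objective trace.
- **Nested leave-one-subject-out cross-validation** with a 121-point
  logarithmic grid search over \((\lambda_1, \lambda_2)\), per-class
  accuracy accounting, and scan-count learning curves.
- **Spatial outputs**: reference-class (placebo-relative) discrimination
  maps, nonzero-coefficient overlap maps, and unthresholded voxelwise
  unpaired t-statistic maps.
- **Evaluation statistics**: confusion matrices, per-class/overall
  accuracies, χ² and exact binomial tests against chance.
- **A synthetic phantom generator** that plants condition-specific spherical
  effect clusters, subject baseline offsets and per-scan voxel noise, so
  the whole pipeline is testable without scan data.

Everything is tidyverse-native: scan collections, cross-validation results
and fold plans are tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Simulate the default phantom study — 15 subjects, three conditions (two
active drugs and placebo), six scans each, four planted effect clusters —
and run the full nested cross-validation:

```r
library(aslpattern)

ds <- generate_phantom_dataset(default_phantom_spec(seed = 0))
ds
#> <phantom_dataset> 15 subjects x 3 conditions x 6 scans on a 14x14x8 grid
#>   180 discriminative voxels in truth mask

cv <- run_nested_cv(ds$scans)   # a few minutes on one core
cv
#> <asl_cv> 15 outer folds, classes: MPH, ATX, PLC
#>   per-class accuracy: MPH 100.0%, ATX 100.0%, PLC 100.0%
#>   overall accuracy: 100.00%

cv$confusion
#>      predicted
#> true  MPH ATX PLC
#>   MPH  15   0   0
#>   ATX   0  15   0
#>   PLC   0   0  15

chisq_vs_chance(cv$confusion)
#> # A tibble: 1 × 4
#>   statistic    df  p_value chance
#>       <dbl> <int>    <dbl>  <dbl>
#> 1        60     2 9.36e-14  0.333
```

Each of the 45 held-out subject-condition images was classified correctly
(planted effects are three times the per-scan noise SD, so this phantom is
deliberately easy); the χ² statistic tests the per-class correct counts
against the 1/3 chance expectation. Discrimination maps localize what drove
the decisions:

```r
dm <- discrimination_maps(cv$final_fit, cv$features, reference = "PLC")
mean(ds$truth_mask[which(dm$MPH != 0 | dm$ATX != 0)])
#> [1] 1
```

— every voxel the classifier used lies inside the planted clusters. On a
noisier companion phantom, accuracy grows with the number of scans
averaged:

```r
lc <- learning_curve(generate_phantom_dataset(learning_curve_phantom_spec(seed = 1))$scans,
                     grid = lambda_grid(1e-4, 1e4, 100), k_values = 1:6)
autoplot(lc)
```

The same statistics apply to recorded outcomes. For a published-style
three-way outcome with 15, 14 and 9 of 15 correct per class:

```r
acc <- class_accuracies(rbind(c(15, 0, 0), c(0, 14, 1), c(1, 5, 9)))
round(100 * acc$overall, 2)
#> [1] 84.44
```

`run_asl_pipeline()` chains simulate → quantify → crossval → maps →
evaluate from one (YAML-able) configuration and writes NIfTI maps, CSV/JSON
tables and a reproducibility manifest.

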