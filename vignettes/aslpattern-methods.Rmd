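---
title: "Methods: perfusion quantification and multi-class pattern recognition in aslpattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perfusion quantification and multi-class pattern recognition in aslpattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`aslpattern` implements a resting-state pharmacological perfusion analysis:
cerebral blood flow (CBF) is quantified from pulsed-continuous arterial spin
labeling (pCASL) control/label image pairs, per-scan flow maps are smoothed,
averaged and mean-centered within subject, and the resulting feature matrix
is fed to a sparse multinomial logistic regression (SMLR) classifier that
discriminates drug conditions under nested leave-one-subject-out
cross-validation (LOO-CV). This vignette documents the models, the tunable
parameters, the numerical choices, and the synthetic phantom on which the
package validates itself.

## CBF quantification

A pCASL acquisition magnetically labels arterial blood water; the
control-minus-label signal difference is proportional to perfusion. With a
coil sensitivity map $C$ (the fully relaxed signal produced by 1 g of water
per ml of brain), flow is

$$\mathrm{CBF} \;=\; \frac{\rho_b\,(S_c - S_l)}
{2\,\alpha\, C\, \omega_a\, T_{1a}\, e^{-\delta/T_{1a}}
\left(1 - e^{-t_l/T_{1a}}\right)},$$

where $S_c$ and $S_l$ are the control and label intensities. The equation
yields ml/(g·s); `quantify_cbf()` multiplies by 6000 to report the
conventional ml/100 g/min. The defaults in `asl_constants()` are:

| constant | meaning | default | unit |
|---|---|---|---|
| `rho_b`  | brain tissue density | 1.05 | g/ml |
| `alpha`  | labeling efficiency × background-suppression efficiency | 0.95 × 0.75 = 0.7125 | — |
| `delta`  | post-labeling delay | 1.5 | s |
| `tl`     | labeling (pulse-train) duration | 1.5 | s |
| `T1a`    | arterial blood longitudinal relaxation | 1.4 | s |
| `omega_a`| water density of blood | 0.85 | g/ml |

Two readings of the protocol constants deserve comment. The labeling
duration is sometimes quoted as a single 500 µs-pulse-based "500 ms" figure
while the full Hanning pulse train lasts 1.5 s; we default to the
pulse-train duration and keep `tl` configurable (a 0.5 s preset is equally
runnable). An arterial-blood T1 below a few hundred milliseconds is
physically impossible at 3 T, so `T1a` is interpreted in seconds (1.4 s),
again configurable.

`estimate_sensitivity_map()` reproduces the neighborhood-maximum
calibration: each voxel takes the maximum intensity of an inversion-prepared
fluid-suppressed calibration image over a cubic neighborhood (avoiding
partial-volume fluid), then divides by the inversion-recovery attenuation
$|1 - 2e^{-TI/T_1}|$ of an assumed reference tissue (white matter:
water concentration 0.735 g/ml, $T_1$ = 0.9 s) and by that water
concentration. The inversion time of the calibration acquisition is
protocol-specific and not derivable from the data; the default `TI = 2` s is
a documented placeholder, which is why the gray-versus-white calibration
agreement is not something this package claims to verify. The calibration is
scale-free by construction: rescaling signal and calibration volumes jointly
leaves the quantified flow unchanged.

`synthesize_asl_pairs()` inverts the equation (control set to the
sensitivity volume, label to control minus the implied perfusion-weighted
difference); quantification then reproduces the input flow map to within
1e-10 relative error, which the test suite asserts as a round-trip identity.

## Preprocessing

`build_feature_matrix()` applies, in order:

1. **Smoothing** (`smooth_volume()`): separable Gaussian with FWHM in mm
   (default 8 mm, the SPM convention for "an 8 mm isotropic kernel"), i.e.
   $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis converted to voxels.
   The kernel is truncated at $4\sigma$ and renormalized; boundaries use
   half-sample symmetric reflection, chosen because it is deterministic,
   reproduces constant volumes exactly, and preserves the in-volume sum for
   symmetric kernels — properties the tests rely on.
2. **Averaging** (`average_scans()`): voxelwise mean of the first $k$ scans
   in acquisition order. Learning-curve subsets always take the *first* $k$
   scans, a deterministic reading of "varying the number of scans".
3. **Within-subject mean-centering** (`mean_center_within_subject()`): basal
   perfusion differs between participants, so each subject's mean image over
   the rows entering the classification problem is subtracted from that
   subject's rows. Centering uses only the selected conditions — the
   two-class problem is centered over two images per subject, the
   three-class problem over three — so the same scans yield different
   matrices for different problems. Centering is idempotent and removes any
   spatially constant subject offset exactly.
4. **Vectorization**: in-mask voxels become feature columns; the analysis
   mask is the set of voxels finite and nonzero in every map of the scan
   set (the acquisition mask of real data; all voxels on phantoms).

A subject with a single row is rejected rather than silently centered to
zero. Smoothing and averaging are both linear, so they commute; the test
suite uses this as a numerical cross-check.

## The classifier

With one-of-$m$ labels $y_{ij}$ and weight vectors $w_j$ per class (no
intercept — inputs are mean-centered), class probabilities are the softmax

$$\pi_{ij} = \frac{\exp(w_j^\top x_i)}{\sum_{k=1}^m \exp(w_k^\top x_i)},$$

the log-likelihood is $L(w) = \sum_{ij} y_{ij} w_j^\top x_i -
\sum_i \log \sum_j \exp(w_j^\top x_i)$, and the fitted weights maximize the
elastic-net objective

$$J(w) = L(w) - \lambda_1 \lVert w \rVert_1 - \lambda_2 \lVert w \rVert_2^2.$$

The L1 term drives exact zeros (a parsimonious, mappable voxel pattern); the
squared-L2 term lets spatially correlated voxels share weight instead of
arbitrarily picking one. The full $m$-column parameterization is trained;
the penalty resolves the softmax shift redundancy, and the reference-class
reparameterization $w'_j = w_j - w_{\mathrm{ref}}$ (`reparameterize_weights()`)
is applied only afterwards for mapping, which provably leaves predictions
unchanged.

### Component-wise optimizer

`fit_smlr()` maximizes $J$ by cyclic coordinate ascent in fixed voxel-major
order, implemented in C++. For each scalar weight the smooth part is
modeled quadratically and the penalty handled exactly, giving a closed-form
soft-threshold update — weights whose unpenalized update falls below the
$\lambda_1$ threshold become exactly zero. Two curvatures are used:

- the *local* curvature $\kappa = \sum_i x_{ij}^2\, p(1-p)$ at the current
  probabilities (a proximal-Newton step, fast in flat regions), and
- the *global* bound $h_j = \tfrac14 \sum_i x_{ij}^2$, which majorizes the
  softmax likelihood's coordinate curvature ($p(1-p) \le 1/4$) and hence
  guarantees ascent.

A Newton step with $\kappa \ge h_j$ is provably an ascent step; otherwise
the exact change in $J$ is evaluated from the maintained softmax state and
a decreasing step is rolled back and replaced by the guaranteed bound step.
The per-sweep objective trace is therefore non-decreasing, which the test
suite asserts. Between full passes the sweep is restricted to the current
nonzero (active) set, the standard acceleration for L1 paths. Initialization
is $W = 0$ (the natural start of a soft-threshold path and fully
deterministic); with $\lambda_1 = 0,\ \lambda_2 > 0$ the objective is
strictly concave and different initializations reach the same optimum, which
is tested against an independent BFGS optimizer of the same objective.

Convergence is declared when the relative objective change per sweep falls
below `tol` (default 1e-6 with a 1000-sweep budget for standalone fits).
Cross-validation fits use the looser `tol = 1e-3`, 25-sweep default:
accuracy-based model selection does not require tightly converged weights,
and fits that hit the budget are counted and reported, not hidden.

## Nested leave-one-subject-out cross-validation

All scans of one subject form the outer test set; each remaining subject is
once the inner validation set, with the other subjects the inner training
set. The `lambda_grid()` default spans $10^{-5}$ to $10^{5}$ in factors of
10 for both penalties — 121 pairs. Within each $\lambda_2$ block the
$\lambda_1$ path is fit from large to small with warm starts. Per-class
accuracy is the fraction of that class's validation rows predicted
correctly, aggregated over inner folds; the selection criterion is the
unweighted mean of per-class accuracies, matching the outer metric.

Ties are common on strong data (whole plateaus of the grid reach the same
validation accuracy). Among tied maxima we select the **largest**
$\lambda_1$, then the **smallest** $\lambda_2$. The first choice picks the
sparsest model. The second deserves a note: at fixed $\lambda_1$, a very
heavy ridge penalty shrinks all weights toward zero *without* zeroing them —
residual gradients stay above the soft threshold across much of the brain —
so large $\lambda_2$ yields denser, more diffuse maps, not sparser ones.
Preferring the smallest tied $\lambda_2$ keeps the selected model
parsimonious and spatially specific.

Within-subject centering is a per-subject operation, so the test subject's
rows are centered by the subject's own mean and no quantity derived from the
test subject can influence training or selection; the test suite verifies
this with a mutation test (replacing a subject's data with noise leaves that
subject's own fold selection unchanged) in addition to the construction
itself. The classifier is refit on all training subjects at the selected
pair and the held-out rows predicted; ties in predicted probability break
deterministically to the lowest class index.

`learning_curve()` repeats the whole procedure using only the first $k$
scans per subject-condition. Averaging suppresses per-scan noise by
$1/\sqrt{k}$, so accuracy rises with $k$ on noisy data and is flat on
noiseless data.

## Spatial outputs

- `discrimination_maps()` places each class's (optionally
  reference-reparameterized) coefficients at their grid coordinates; the
  reference map is identically zero and out-of-mask voxels are `NA`.
- `compute_overlap_map()` categorizes voxels by the exact-zero pattern of
  two maps (neither / only A / only B / both). "Nonzero" is an exact test —
  the L1 path produces exact zeros, so no epsilon threshold is applied.
- `unpaired_t_map()` computes the voxelwise two-sample pooled-variance
  (Student) t-statistic for one binary contrast from the same images used to
  train the classifier. Pooled rather than Welch variance because the
  designs are equal-$n$ and the statistic is meant as the simplest
  univariate analogue of the classifier; maps are returned unthresholded,
  with `NaN` where the pooled variance vanishes.
- `sign_concordance()` reports the fraction of voxels, among those with
  nonzero map coefficients and defined t, where the two agree in sign — the
  qualitative check that multivariate weights point the same way as focal
  univariate effects.

## Evaluation statistics

`confusion_matrix()` / `class_accuracies()` define per-class accuracy as the
confusion diagonal over row totals and overall accuracy as their unweighted
mean. `chisq_vs_chance()` tests the per-class correct counts against the
chance expectation $E_c = n_c/m$ with $\chi^2 = \sum_c (O_c - E_c)^2/E_c$,
$df = m-1$; for a 15-per-class three-way design with 15, 14 and 9 correct
this gives $\chi^2 = (10^2+9^2+4^2)/5 = 39.40$ at $p = 2.78\times 10^{-9}$.
`binomial_vs_chance()` is the one-sided exact upper tail
$P(X \ge k)$, $X \sim \mathrm{Bin}(n, \text{chance})$. For 28 of 30 correct
at chance 0.5 the exact tail is $466/2^{30} \approx 4.34\times10^{-7}$;
a sometimes-quoted $2.89\times10^{-8}$ corresponds to $P(X \ge 29)$, i.e.
miscounting 93.33% of 30 as 29 correct — the implementation keeps the
standard definition and documents the difference rather than reproducing it.
No continuity corrections are applied anywhere.

## The synthetic phantom

No public scan data accompany the analysis this package operationalizes, so
`generate_phantom_dataset()` supplies inputs with exactly the statistical
structure the pipeline assumes:

$$x_{s,c,k}(v) = \mathrm{baseline} + b_s + \Delta_c(v) + \varepsilon,
\qquad b_s \sim N(0, \sigma_{\mathrm{subj}}^2),\quad
\varepsilon \sim N(0, \sigma_{\mathrm{noise}}^2)\ \text{i.i.d.},$$

with $\Delta_c$ the sum of spherical cluster effects for condition $c$
(Euclidean voxel-center membership, boundary ties included). The defaults
emulate the motivating study design: 15 subjects × 3 conditions
(two active drugs and placebo) × 6 scans, 3 mm voxels, baseline
50 ml/100 g/min, subject offset SD 8 and per-scan voxel noise SD 4 —
values in the range reported for resting gray-matter perfusion and
between-subject variability. Four clusters mimic the clearest differential
patterns such studies report: a caudate-like region responding to one drug
only, midbrain- and thalamus-like regions where the drugs push flow in
opposite directions, and a cerebellum-like region responding to the other
drug; effect magnitudes (12–15 ml/100 g/min) are at least three times the
per-scan noise SD. Effect sizes are free parameters of the phantom, not
estimates of real drug effects. The default grid is deliberately small —
14 × 14 × 8 voxels — large enough to hold four well-separated clusters yet
small enough that the full 121-pair nested LOO-CV runs in a few minutes on
one core. The `truth_mask` marks the union of spheres whose effect vectors
differ between any two conditions, i.e. the voxels a condition classifier
may legitimately use.

What the phantom does *not* emulate: spatial autocorrelation of
physiological noise, motion and registration error, k-space/readout
artifacts, partial-volume structure, or spatially varying baseline anatomy.
Subject offsets are spatially constant scalars by design — precisely the
component that within-subject centering removes, making that step testable.
Consequently, a passing phantom suite demonstrates correctness of the
pipeline's statistical machinery, not expected accuracy on real scans.

Study-condition sizes used by the validation suite, chosen once as a
balance between statistical resolution and a few minutes of single-core
runtime: the strong-effect and null (zero-effect) phantoms use the default
design above with the full 121-pair grid; the learning-curve trend uses 10
phantom seeds on a reduced companion design
(`learning_curve_phantom_spec()`: 6 subjects, 10 × 10 × 6 grid, 5 × 5
penalty grid, per-scan noise SD 30) whose noise level places single-scan
accuracy mid-range so the benefit of averaging is visible rather than
saturated.

## Known limitations

- Single-delay quantification only; no multi-delay kinetic modeling,
  partial-volume correction, or magnetization-transfer physics.
- Inputs are assumed co-registered on a common grid; the package never
  resamples, and figure-space (Talairach/MNI) conventions are out of scope.
- The optimizer's active-set sweeps are tuned for the LOO-CV workload;
  extremely under-regularized separable problems (both penalties ~1e-5) may
  exhaust the sweep budget and return `converged = FALSE` — such fits are
  reported honestly and counted by `run_nested_cv()`.
- The χ² test on per-class correct counts treats classes as independent
  binomials at chance, the conventional reading for balanced designs; it is
  not a test of the full confusion structure.
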