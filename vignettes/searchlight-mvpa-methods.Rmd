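---
title: "Methods: searchlight MVPA of sexually dimorphic gray-matter morphometry"
author: "dimorphMVPA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: searchlight MVPA of sexually dimorphic gray-matter morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis chain

`dimorphMVPA` implements a complete chain for asking whether, and where,
two groups of subjects (here: girls and boys, within an autism or a
typically developing cohort) differ in symptom profile and in gray-matter
(GM) morphometry:

1. **Symptom-domain statistics.** Pooled-variance two-sample t-tests per
   ADI-R domain (social, communication, repetitive/restricted behavior,
   total), a 2x2 group-by-sex ANOVA of demographic variables (type-II sums
   of squares via `car::Anova`), and an L1-penalized logistic classifier
   of sex from the three domain scores with leave-one-out cross-validation
   (LOOCV), fitted with `glmnet`.
2. **Mass-univariate morphometry.** Voxelwise t maps from the linear
   model `GM ~ group + age + site` and type-II F maps from
   `GM ~ group * sex + age + site`, computed by shared-design linear
   algebra over all in-mask voxels at once.
3. **Searchlight MVPA.** At every in-mask voxel, the multivoxel pattern
   of its 3x3x3 neighborhood (27 features) is classified with an
   RBF-kernel SVM; the regularization parameter C and the kernel width
   alpha are grid-searched over {0.125, 0.25, 0.5, 2, 16, 32} x
   {0.125, 0.25, 0.5, 2, 16, 32} with M = 10-fold cross-validation, and
   the maximal cross-validation accuracy (CA) is mapped. Under the null
   hypothesis of exchangeable labels the number of correct predictions is
   modeled as Binomial(N, chance), giving a voxelwise upper-tail p. Maps
   are thresholded at a familywise-corrected height threshold and a
   cluster-extent threshold calibrated by Monte-Carlo simulation of
   smoothed Gaussian null fields on the analysis mask (the AlphaSim
   construction), and surviving clusters are reported with their peak
   coordinate (world mm) and peak accuracy.
4. **Brain-behavior SVR.** For each surviving cluster an 8 mm sphere is
   centered at its peak-accuracy voxel (the deterministic replacement for
   visual peak selection), and the multivoxel GM pattern of the sphere
   predicts one symptom domain with nu-support-vector regression (RBF
   kernel, C = 1, nu = 0.05) under LOOCV. Significance comes from a
   permutation null (1000 surrogates by default) and Benjamini-Hochberg
   FDR across the ROIs of the analysis.

The pipeline runs end-to-end on synthetic cohorts with known ground truth
(`generate_symptom_cohort()`, `generate_gm_cohort()`), so every stage is
testable without access to restricted clinical repositories.

# The synthetic-cohort generator

The generator emulates the *statistical structure* of a two-cohort study:

* a large symptom-only cohort (128 girls vs 614 boys with ASD, one site),
  and
* a four-cell imaging cohort (25/25 ASD girls/boys, 19/19 TD girls/boys,
  six sites contributing equally to every cell).

Scores are Gaussian on a latent scale with conventional ADI-R
diagnostic-algorithm ranges (social mean 20, SD 6, range 0-30;
communication 16, 5, 0-26; RRB 6, 2.5, 0-12 in the ASD group; TD children
score near the floor), then rounded to integers and clipped. Rounding and
clipping attenuate small standardized differences by a few percent; the
recovery test at n = 500/cell verifies the realized Cohen's d within 0.15
of the request. The preset between-sex effects are the standardized
differences implied by the published group sizes and t statistics
(`d = t * sqrt(1/n1 + 1/n2)`), dominated by reduced RRB severity in girls
(d = -0.50 in the large cohort); the source study never prints domain
means or SDs, so the score scales themselves are conventional choices,
not calibrated values.

Volumes are built as
`smooth(baseline + patterns + age slope + site shift + noise)` on a
desk-scale grid (default 32^3 voxels at 3 mm, ellipsoidal mask, 6 mm FWHM
smoothing, baseline 0.5, noise SD 0.1), mirroring the
segment-modulate-smooth order of VBM. Two implantable ground-truth
effects matter:

* **Mean-shift patterns** add +/- amplitude/2 by class at the ROI voxels:
  visible to univariate and multivariate analysis alike.
* **Covariance patterns** split the ROI into two contiguous half-blocks
  and add a per-subject sign `z = +/-amplitude` with equal signs on the
  two halves in one class and opposite signs in the other. The signs are
  balanced within each class, so per-voxel class means are exactly zero
  in every finite sample while the half-to-half correlation flips sign
  between classes. Univariate maps are blind to this structure by
  construction; a multivoxel classifier separates it easily (CV accuracy
  above 0.8 already at amplitude = 2 x noise SD). This is the generator's
  ground-truth version of the dissociation the pipeline is designed to
  exhibit: no univariate differences, high searchlight accuracies.
* **ROI-symptom couplings** impose a target correlation r between an
  ROI's mean GM and one domain score within one `group.sex` subgroup.
  The coupling slope is calibrated against the *realized* nuisance + noise
  SD of the ROI mean (`slope = sd(roi mean) * r / sqrt(1 - r^2)`), which
  makes the induced correlation — and the downstream SVR power —
  invariant to the chosen noise level.

Each subject draws from an RNG substream derived from `(seed, subject
index)`, so identical specs reproduce byte-identical cohorts and growing
a cell never reshuffles existing subjects.

What the generator does *not* emulate: anatomy (the mask is an
ellipsoid), tissue segmentation, scanner physics, realistic spatial
autocorrelation beyond the single smoothing kernel, missing data, and
item-level score structure. Passing tests therefore demonstrate that the
*machinery* is correct and calibrated under known ground truth — not that
any particular clinical effect exists in real data.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| searchlight half-width | 1 (27 voxels) | voxels | the classical 3x3x3 searchlight |
| C, alpha grids | {0.125, 0.25, 0.5, 2, 16, 32} | — | the printed six-point grid, taken verbatim |
| M (CV folds) | 10 | — | standard M-fold CV |
| `min_in_mask` | 14 | voxels | skip searchlights with fewer than 14 in-mask neighbors (half the block plus center) |
| height threshold | p = 0.001, Bonferroni over evaluated voxels | — | "FWE corrected" realized as Bonferroni, the only method computable from the stated ingredients; a max-statistic permutation mode is available |
| cluster threshold | p = 0.01, `k_min` from >= 500-1000 simulations | voxels | AlphaSim-style extent calibration, recomputed for the analysis grid (never hard-coded) |
| SVR | C = 1, nu = 0.05, radius 8 mm | — | the printed settings |
| smoothing | 6 mm FWHM (generator), sigma = FWHM/2.355 | mm | separable truncated-at-4-sigma Gaussian, unit-sum kernel |

# Numerical and design choices

**Searchlight engine.** The per-voxel grid search (36 SVM fits x 10
folds at every mask voxel) is the computational core, so the RBF C-SVC is
solved by a compact SMO implementation in compiled code (libsvm's
working-set selection and stopping rule, duality-gap tolerance 1e-3,
precomputed kernels — every searchlight problem has at most a few hundred
subjects). The same applies to the nu-SVR used in the brain-behavior
stage. Both solvers are validated in the test suite against the reference
libsvm implementation (`e1071`): decision values and predictions agree to
the SMO tolerance across random problems. Features are standardized with
training-fold statistics inside every fold; zero-variance (padded)
features map to 0. Grid ties break toward the smallest C, then the
smallest alpha (prefer the least complex model, deterministically). One
stratified fold assignment per run is shared across voxels so that
spatial accuracy variation is never confounded with fold resampling
noise. CA aggregates total correct over all folds divided by N, so
unequal fold sizes cannot bias the binomial k.

**Covariates.** Age and site are removed by voxelwise regression
residuals. For classification stages the default removes them on the
whole sample before cross-validation, matching the global "covariates of
no interest" convention of classical VBM tooling; a cross-fitted mode
(`covariate_mode = "fold"`, nuisance fits estimated with each training
fold and applied to its test fold) is provided as the statistically safer
variant.

**Binomial null.** `p = P(X >= k)`, `k = round(CA * N)`,
`X ~ Binomial(N, chance)` with chance = majority-class proportion. The
grid search's max-over-36 introduces a small optimism bias in null CA
(quantified in the tests: null mean CA ~ 0.55 for n = 40); the binomial
null absorbs it only partly, which is why inference additionally requires
the Monte-Carlo cluster extent. The specificity test (20 label-permuted
cohorts through the full pipeline) verifies that the combined threshold
yields at most one false-positive cohort.

**Monte-Carlo extent.** Null fields are simulated as iid Gaussians,
smoothed to the stated FWHM, standardized by the theoretical
post-smoothing SD (`prod(sqrt(sum(k_axis^2)))`, exact for interior
voxels), thresholded at `qnorm(1 - height_p)`, and labeled with
6-connectivity (faces; 18/26 available). `k_min` is the smallest size
whose null probability of appearing anywhere in the mask is at most
`cluster_p`. At FWHM 0 this reduces to iid voxels and is checked against
a brute-force flood-fill enumeration.

**SVR R-squared.** The R^2 of observed vs LOOCV-predicted scores defaults
to the explained-variance definition `1 - SSE/SST`, with the squared
Pearson correlation available as `r2_method = "pearson"`. The reason is a
pitfall worth documenting: with C = 1 and nu = 0.05 the dual budget
`C * nu * n` admits roughly one support vector, the fitted function is
nearly flat, and its LOOCV predictions are dominated by the leave-one-out
training-mean artifact — they *anti*-correlate with the held-out scores
(removing subject i shifts the training mean away from y_i). The squared
Pearson correlation is blind to that sign, so under the null it
concentrates around 0.3-0.5 and a genuine signal (which cancels part of
the anti-correlation) can score *lower* than the null: the permutation
test loses, and can even invert, its power. The SS definition scores
squared error, which genuine signal always reduces; with it the
permutation p is uniform under the null and the coupled-ROI power
criterion is met. The same artifact is why the ADI-R classifier's LOOCV
accuracy under permuted labels sits *below* 0.5 on balanced data (the
leave-one-out majority artifact): the permuted-label check is therefore a
one-sided guard — accuracy must not exceed the upper binomial bound.

**SVR preprocessing and kernel width.** Features and scores are
standardized after covariate removal (the usual `svm-scale`
preprocessing), so the fixed (C, nu) budget acts on a common scale. The
default kernel width is the median heuristic, `gamma = 1 / median
(squared inter-subject distance)`; the `1/(n_features * variance)`
convention is a special case the user can pass explicitly. The median
heuristic measurably stabilizes power when feature noise is spatially
correlated by smoothing.

**Permutation null with covariates.** Surrogate score vectors are
re-residualized on the nuisance design after shuffling (the
Freedman-Lane scheme). A naive shuffle of residualized scores is
demonstrably anti-conservative here: with six small site cells the
residualizing projection writes the same within-site structure into
features and scores, which the SVR can exploit in the observed pairing
but the shuffle destroys. The strict counting p-value `#{R_i^2 > R^2} /
n_perm` is reported as printed (no add-one correction), alongside the
add-one estimator and the tie count.

**Sparse classifier.** Lasso logistic regression; the penalty is chosen
inside each LOOCV fold by internal 10-fold CV on misclassification loss
with the 1-SE rule. Misclassification (not deviance) is used because,
with a perfectly separating feature, the deviance decreases monotonically
along the entire path and the 1-SE rule would retain spurious tiny
coefficients; the class-loss rule recovers the expected behavior (only
the separating feature selected, LOOCV accuracy 1). On the imbalanced
128-vs-614 preset with the calibrated d ~ 0.5, the selected model is
honestly the intercept-only majority classifier (raw accuracy 82.7% =
the majority rate, balanced accuracy 50%); both accuracies are reported
because the published accuracy's imbalance handling is unstated.

**Degenerate inputs.** Voxels with zero residual variance yield NaN
statistics plus a warning (never a silent p = 1); constant scores,
single-class labels, empty ROIs, rank-deficient designs (with the aliased
columns named) and mask/grid mismatches raise errors.

# Problem sizes used by the test and acceptance suites

All validation runs are desk-scale by design: 5^3 oracle-equivalence
searchlights (12 subjects), the full dissociation run at 32^3 / 3 mm with
25 girls and 25 boys with ASD, specificity over 20 label-permuted
cohorts at 20^3 with 15 + 15 subjects and 500 extent simulations,
extent-oracle enumeration at 4^3 with 1e5 simulations, SVR calibration
with 100 null runs x 200 surrogates and power over 25 seeded cohorts at
24^3. These sizes were chosen so that each property is tested with
meaningful statistical resolution (e.g. the specificity grid uses 15+15
subjects because with 10+10 the Bonferroni height threshold can never be
crossed and the test would be vacuous) while the whole suite runs on a
single CPU in minutes.

# Known limitations

* The ellipsoidal mask and stationary smoothing understate the spatial
  heterogeneity of real GM masks; `k_min` must be recomputed for any real
  grid and smoothness (the package never hard-codes an extent).
* Bonferroni height correction is conservative for smooth CA maps; the
  permutation max-statistic mode is costlier but exact.
* The binomial null treats LOOCV/M-fold predictions as independent
  Bernoulli trials, which they are not exactly; the Monte-Carlo extent
  and the permutation-specificity test are the calibrated backstops.
* nu-SVR at the printed (C = 1, nu = 0.05) is heavily regularized; its
  absolute R^2 values are small even for strong couplings, and inference
  should rest on the permutation p, not on the R^2 magnitude.
* ADI-R scores are modeled as rounded Gaussians; no item-level or
  ordinal structure, no missingness.
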