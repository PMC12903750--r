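---
title: "Habitat radiomics: models, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics: models, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Solid tumors are spatially heterogeneous: a necrotic core, a proliferative
rim and intermediate zones can coexist within one lesion, and aggregate
("whole-tumor") radiomic features average this structure away. Habitat
radiomics partitions each tumor into spatially distinct subregions
("habitats") by clustering voxel-level imaging descriptors, then extracts
texture features per habitat, so that regional phenotypes — for example a
rim/core intensity contrast — become explicit predictors. `habrad`
implements this pipeline end to end for 3D CT-like volumes with binary
tumor masks: preprocessing and harmonization, voxel descriptor maps,
k-means habitat partitioning with Calinski–Harabasz (CH) model selection,
IBSI-style feature families (first-order, shape, GLCM, GLRLM, GLSZM, and
intensity/wavelet image filters), LASSO-based signature construction inside
nested cross-validation, and a full evaluation layer (DeLong-compared ROC,
Hosmer–Lemeshow calibration, decision curves, a points-based nomogram).

Because no patient imaging is distributed with the package, a synthetic
multi-center cohort generator with *planted* habitat structure provides
ground truth for every stage. All validation claims below are claims about
that generator's conditions, not about clinical data.

## Preprocessing

`resample_isotropic()` brings anisotropic acquisitions (slice thickness up
to several mm) to a 1 mm isotropic grid — trilinear interpolation for the
volume, nearest-neighbor for the mask so it stays binary; the world extent
of the voxel-center grid is preserved to within one voxel.
`denoise_gaussian()` smooths with a physical-units sigma converted per axis,
and `normalize_intensity()` rescales to the 0–255 range (within the mask if
one is supplied; a constant region maps to 0 by an explicit degenerate
rule).

Harmonization is performed at the *feature* level (`combat_harmonize()`),
the standard radiomics practice, with location/scale ComBat and parametric
empirical-Bayes shrinkage. The fit/apply split matters: the model is
estimated on the training cohort only and applied frozen to validation and
test cases, which prevents leakage but requires every batch to be present
in the training cohort. The synthetic cohort therefore distinguishes
*centers* (which define the train/validation/test splits) from *scanners*
(the CT machines, drawn per case across all centers); the scanner is the
batch axis ComBat removes. With shrinkage disabled the per-batch moments
are removed exactly, which is the closed-form identity the tests assert;
with shrinkage enabled the estimates agree with the `sva` reference
implementation.

Feature reliability against segmentation variability is screened by
`case_icc_gate()`: the two-way random-effects, absolute-agreement,
single-rater ICC(2,1) between features from two raters' masks, retaining
features with ICC at or above 0.85. The absolute-agreement variant is
chosen deliberately — a systematic offset between raters should count
against a feature. `simulate_second_rater()` produces the second rater by
thresholding the smoothed mask indicator plus a correlated noise field
(default 1 mm jitter, Dice ≈ 0.98 on a 20 mm sphere).

## Texture features

The gray-level matrices follow the IBSI consensus choices: discretization
into 32 equal-width bins inside the ROI (`width = (max − min)/n_bins`,
minimum maps to level 1, maximum to the top level), 13 unique 3D directions
at distance 1 with symmetric accumulation and direction-averaged features
for GLCM/GLRLM, and 26-connected zones for the direction-free GLSZM. Every
matrix implementation is tested for exact equality against an independent
exhaustive-enumeration oracle (voxel-pair loops, line walks, flood fill) on
random small ROIs, and the degenerate identities of a constant ROI
(Contrast 0, JointEnergy 1, single zone) are asserted directly.

Shape features use the voxel-count volume and a mesh surface area from
marching tetrahedra over the mask indicator. The indicator is lightly
smoothed (Gaussian, 0.6 voxel) before iso-surfacing at 0.5 with linear
edge interpolation: meshing the raw binary mask overestimates the area of
curved surfaces by a staircase bias large enough to push the sphericity of
a 10 mm digital sphere down to ~0.78 (and even a reference marching-cubes
implementation gives ~0.91), while the smoothed mesh recovers ~0.96. The
cost is a few percent underestimate on sharp-edged solids such as cubes —
an accepted trade-off, since tumors are smooth, that the cube test covers
with a correspondingly wider tolerance.

Image filters cover `square`, `squareroot`, `logarithm`, `exponential`
(range-normalized pointwise maps) and `wavelet`, a single-level separable
3D Haar decomposition producing the eight LLL…HHH subbands mapped back to
the input shape. A local-binary-pattern filter is deliberately out of
scope.

## Habitat mapping

`compute_voxel_feature_map()` computes a five-channel descriptor per
in-mask voxel: the voxel's own intensity, and the window statistics of the
`(2r+1)^3` neighborhood intersected with the mask — local mean, local
population variance, local histogram entropy (16 global bins) and local
GLCM contrast (mean squared level difference over distance-1 pairs). All
window statistics use cumulative-sum box filters, so the map costs a few
linear passes over the volume.

Two design choices here deserve explanation, because both were forced by a
measurable failure mode rather than taste:

* **The intensity channel.** Window statistics are spatially blurred: a
  voxel within `r` voxels of a habitat interface mixes both habitats. For
  thin habitats — and equal-volume concentric shells are only 1–2 voxels
  thick at realistic tumor sizes — even an oracle classifier on the local
  mean cannot exceed an adjusted Rand index of about 0.8 against the
  planted labels. The center voxel's own intensity, by contrast, is an
  unblurred sample of its habitat. Carrying it as the first channel makes
  near-perfect recovery possible.
* **Channel weights (3, 2, 1, 1, 1).** The second-order channels (variance,
  entropy, contrast) respond to habitat *interfaces* as strongly as to
  interiors; at equal weight these interface responses form their own mass
  in descriptor space, seize k-means centers and drag the remaining centers
  off the habitat modes (observed ARI ≈ 0.7 on the four-habitat phantom).
  Down-weighting them — while keeping them, because they regularize the CH
  curve against over-splitting the intensity axis — restores ARI ≈ 1.0.
  The weights are a fixed package default, chosen during method design on
  the phantom construction and frozen before the validation suite was
  written.

The default window radius is 1 (configurable): at 1 mm isotropic
resampling and centimeter-scale tumors, radius-2 windows blur enough that
CH selection over-segments (modal K = 6 on the K = 4 phantom).

`partition_habitats()` runs `stats::kmeans` (10 restarts, per-k derived
seeds) for each k in 2–10, scores each partition with the CH index
(`(B/(k−1))/(W/(n−k))`, tested against a direct-summation oracle), picks
the maximizing k with ties resolved to the smallest k (parsimony), and
renumbers labels 1..K by ascending within-habitat mean intensity so that
habitat indices are stable across restarts and comparable across cases.
Clustering is per patient; `harmonize_habitat_count()` reconciles the
cohort either to the modal per-case optimum (default, re-clustering every
case at K*) or keeps per-case optima aligned by the intensity-ranked index.
Per-habitat features reuse the whole-tumor machinery on each habitat
submask with `_habK` name suffixes plus volume fractions; habitats below 10
voxels yield flagged missing values (imputed from the training split
downstream) so the schema is identical across cases.

## Modeling

Features are z-scored with training-split statistics only (population
standard deviation; zero-variance features dropped), selection is by
L1-penalized logistic regression over glmnet's lambda path with stratified
10-fold cross-validation (an MSE-on-{0,1} mode is available for the
squared-error reading of signature selection), and the default imaging
signature is the *penalized fit itself* at the optimal lambda
(`lasso_signature_model()`): the shrunk linear predictor through the
logistic function. An unpenalized refit on the selected features is also
available (`fit_classifier()`), but its saturated probabilities on small
training cohorts make downstream score combination unstable. Classifiers
cover SVM (linear/polynomial/RBF kernels, Platt probabilities), random
forest and extra-trees (ranger, depth 1–5), gradient-boosted trees
(xgboost, depth 1–5, up to 100 rounds) and plain logistic regression, all
behind an exhaustive, seeded, stratified-CV grid search with pooled CV AUC
as the selection metric. Decision thresholds are Youden-optimal on the
training predictions and frozen thereafter.

`nested_cross_validate()` keeps standardization, selection and any grid
search strictly inside each outer-training part, pooling the held-out
predictions into an unbiased CV AUC; a deliberately leaky variant
(`naive = TRUE`, selection on all rows first) is retained only to
demonstrate the optimism nesting removes, and the tests assert it is
optimistic on pure noise.

The clinical layer (`fit_logistic_signatures()`) provides univariable
logistic fits with Wald odds-ratio CIs per covariate, a multivariable fit
over the univariably significant covariates (p < 0.05), and the combined
signature: a logistic model on cT stage (ordinal 1/2/3) plus the radiomics
and habitat scores. The scores entering the combined model are each
component model's predicted probabilities; inside `run_study()` the
combined weights are *stacked* — fit on out-of-fold training scores on the
logit scale — so they reflect held-out rather than resubstitution skill.
Complete separation is detected and refit with a light ridge penalty.

## Evaluation

AUC is the tie-aware mid-rank Mann–Whitney statistic; its variance and the
95% CI come from the DeLong structural components, and paired model
comparisons use the component covariance (pairwise matrix mode for several
models; no multiplicity correction by default, with Holm behind a flag).
The implementation is cross-checked against `pROC` and a jackknife
variance oracle, and its type-I error is Monte-Carlo-calibrated at n = 200.
Confusion metrics report undefined ratios as missing rather than zero.
Calibration uses deciles-of-risk bins with the Hosmer–Lemeshow statistic on
`bins − 2` degrees of freedom — appropriate for probabilities from a fitted
logistic model, which is how the calibration simulations are constructed
(the same statistic on *true* generative probabilities would need `g`
degrees of freedom and over-rejects at `g − 2`). Decision curves implement
`NB(t) = TP/n − (FP/n)·t/(1−t)` with treat-all/treat-none references on a
0.01–0.80 grid.

The nomogram maps the combined logistic model to a 0–100 points scale with
the standard regression-nomogram construction: the variable with the
largest |coefficient| × range spans exactly 0–100, references sit at each
variable's risk-minimizing end, and total points map affinely to the linear
predictor, so chart predictions agree with the model to well under 0.01
probability.

## The synthetic cohort: what it emulates, and what it does not

`phantom_spec()`/`generate_phantom()` build ellipsoidal tumors of K
contiguous habitats — equal-volume concentric shells by default (rim/core
biology), Voronoi cells as an alternative — filled with spatially
correlated Gaussian texture (filtered white noise, correlation length 1.5
voxels) at per-habitat means 40/90/150/210 and sd 5, plus additive noise
(sd 2), on a 32³ grid at 1 mm spacing with a 12 mm radius. These defaults
are the package's reference study conditions.

`cohort_spec()`/`generate_cohort()` draw per-case habitat parameters
(mean jitter sd 15, radius jitter 1 mm), compute ground-truth habitat
summaries, and draw binary outcomes from a logistic model on z-scaled truth
features whose intercept is calibrated by root-finding to a target
prevalence of 0.3 (≈ the pathological complete-response rate in
esophageal-cancer neoadjuvant series). The default outcome coefficients,
(+1.6, −1.6) on the two middle habitat means, are a deliberate
construction: their difference cancels exactly in any volume-weighted
whole-tumor mean, so habitat-level features carry the only true imaging
signal and whole-tumor aggregates retain at most a weak echo through the
pooled spread. The clinical table mirrors a typical baseline table (age ~
N(65, 6.5), sex, BMI ~ N(22.7, 2.4), cT in {T1, T2, T3} correlated with
the outcome through a latent shift of 1.2, giving a clinical AUC near 0.7
— in the range the reported cT odds ratios imply; cN independent). Cohort
sizes default to the 101/43/117/75 train/validation/test1/test2 structure.

`simulate_signature_cohort()` is the feature-table-level counterpart used
by `run_study()`: measured habitat features are the truth summaries plus
measurement noise (sd 5) and 20 uninformative columns; whole-tumor
radiomics features are volume-weighted aggregates of the same parameters
plus their own noise columns; per-scanner shifts (0.6 feature-sd) are the
batch effect ComBat removes. Running the four-signature comparison on
feature tables rather than re-rendering hundreds of volumes is what makes
a 20-seed replication study affordable; the image-level path (render,
preprocess, extract, cluster) is exercised end to end on a small rendered
cohort in the test suite and the acceptance script's phantom checks.

What the generator does **not** emulate: CT physics (beam hardening, HU
calibration), anatomy and organ context, deformable inter-rater
disagreement beyond boundary jitter, non-Gaussian texture, habitat shapes
more complex than shells/Voronoi cells, and any coupling between clinical
covariates and imaging beyond cT–outcome. Passing the validation suite
therefore shows the *machinery* is correct and the comparison *structure*
(habitat ≥ whole-tumor when only habitat-level structure is predictive)
is recoverable — not that any particular clinical AUC would replicate.

## Numerical choices and problem sizes

Determinism: every generator and fit is a pure function of its inputs
including the seed; k-means restarts, CV folds and classifier seeds derive
from the caller's seed. Ties in CH resolve to the smallest k; Youden ties
to the lowest threshold; degenerate inputs (constant ROI, zero-variance
features, single batch, habitats under 10 voxels) follow explicit rules
rather than erroring where the pipeline can continue meaningfully.

The validation suite runs at deliberately modest sizes — 6³ ROIs for the
exhaustive texture oracles (50 replicates), 32³ phantoms (~7,200 tumor
voxels) over 20 seeds for habitat recovery, n = 200 × 1000 simulations for
DeLong size, n = 2000 × 1000 for calibration, n = 400 with 100 features
for nested-CV signal recovery, and 20 seeds of the 336-case feature-level
study for the ordering replication. These sizes were chosen so the full
suite completes in a few minutes on one CPU while leaving the Monte-Carlo
tolerances meaningful.

## Known limitations

* Per-patient clustering with intensity-ranked label alignment is one of
  several defensible readings of habitat analysis; pooled-cohort voxel
  clustering is not implemented.
* The descriptor weighting is tuned to intensity-dominant habitat
  structure; habitats distinguished *only* by second-order texture at
  identical mean intensity would need different weights (they are a
  single argument away).
* The surface-area mesh trades sharp-edge accuracy for curved-surface
  accuracy, as described above.
* Feature-level ComBat assumes additive/multiplicative batch effects on
  features; voxel-level harmonization is not attempted.
* The paper-style headline AUCs depend on private patient data and are not
  reproducible here; the package's claims are the property-based ones its
  tests and acceptance script compute.
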