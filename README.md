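# habrad — habitat radiomics for 3D tumor imaging

`habrad` implements a habitat-radiomics pipeline for 3D tumor imaging:
partitioning each tumor into spatially distinct subregions ("habitats") by
k-means clustering of voxel-level texture descriptors, extracting radiomic
features per habitat, and building and evaluating predictive signatures of
a binary treatment outcome (such as pathological complete response after
neoadjuvant chemoimmunotherapy). It is aimed at methodologists who want a
tested, fully reproducible reference implementation of every stage of such
a study, with a synthetic multi-center cohort generator that plants known
habitat structure so each stage can be validated against ground truth.

## What it computes

* **Preprocessing** — isotropic resampling (trilinear volume /
  nearest-neighbor mask), Gaussian denoising in physical units, 0–255
  intensity normalization, feature-level ComBat harmonization (parametric
  empirical Bayes, fit on training cases and applied frozen to held-out
  cases), and an inter-rater reliability gate retaining features with
  ICC(2,1) ≥ 0.85.
* **Features** — first-order statistics, mesh-based shape descriptors
  (sphericity `π^{1/3}(6V)^{2/3}/A`), and IBSI-style gray-level matrices:
  GLCM and GLRLM over the 13 unique 3D directions at distance 1
  (direction-averaged) and the 26-connected GLSZM, plus square /
  square-root / logarithm / exponential and single-level 3D Haar wavelet
  image filters. Matrices are tested for exact equality against
  exhaustive-enumeration oracles.
* **Habitat mapping** — per-voxel descriptors (own intensity + window
  mean / variance / entropy / GLCM contrast), k-means over k = 2..10 with
  Calinski–Harabasz model selection
  `CH(k) = (B/(k−1)) / (W/(n−k))`, intensity-ranked label
  renumbering, per-habitat feature extraction with `_habK` suffixes, and
  cohort-level habitat-count harmonization.
* **Modeling** — training-split standardization, L1-penalized logistic
  LASSO selection with stratified 10-fold CV, the penalized signature as
  the default score, optional SVM / random-forest / extra-trees /
  gradient-boosting classifiers behind a seeded exhaustive grid search,
  nested cross-validation with in-fold selection, and clinical /
  combined logistic signatures (combined = logistic on cT stage + the
  radiomics and habitat scores, stacked on out-of-fold training scores).
* **Evaluation** — mid-rank AUC with DeLong variance, CIs and paired
  DeLong comparisons (pairwise matrix, optional Holm adjustment),
  confusion metrics at the training-frozen Youden threshold,
  Hosmer–Lemeshow calibration on risk deciles, decision-curve analysis
  `NB(t) = TP/n − (FP/n)·t/(1−t)`, and a points-based nomogram that
  round-trips to the logistic model within 0.01 probability.
* **Synthetic cohort** — multi-center phantoms (concentric-shell or
  Voronoi habitats, correlated Gaussian texture, scanner batch effects,
  two simulated raters) and a logistic outcome model on ground-truth
  habitat summaries with a prevalence-calibrated intercept.

## Worked example

```r
library(habrad)

# a 4-habitat phantom: 32^3 grid, 12 mm tumor, shell means 40/90/150/210
ph <- generate_phantom(phantom_spec(seed = 7))
fm <- compute_voxel_feature_map(ph$volume, ph$mask)
hm <- partition_habitats(fm, seed = 7)
hm
#> <habitat_map> K = 4 habitats over 7208 voxels (CH-selected)
round(hm$ch_scores)
#>     2     3     4     5     6     7     8     9    10
#> 18262 16484 25996 24735 22575 21193 20436 19201 18120
```

The CH curve peaks at k = 4, matching the planted habitat count, and the
recovered labels agree with the planted ones (adjusted Rand index ≈ 1.0
across seeds). Per-habitat features recover the planted intensities —
habitat 1 is the tumor core, habitat 4 the rim:

```r
hf <- extract_habitat_features(ph$volume, hm)
round(hf[c("original_firstorder_Mean_hab1", "original_firstorder_Mean_hab4",
           "habitat_volume_fraction_hab1")], 3)
#> original_firstorder_Mean_hab1 original_firstorder_Mean_hab4
#>                        37.948                       209.515
#>  habitat_volume_fraction_hab1
#>                         0.241
```

The full four-signature comparison study on a simulated 336-case
multi-center cohort (train/validation/test1/test2 = 101/43/117/75), where
only habitat-level features carry true imaging signal:

```r
rep1 <- run_study(seed = 1)
rep1
#> <study_report> AUC by cohort and signature
#>  signature train   val test1 test2
#>   Clinical 0.697 0.644 0.746 0.694
#>  Radiomics 0.909 0.532 0.451 0.512
#>    Habitat 0.899 0.863 0.891 0.957
#>   Combined 0.951 0.815 0.859 0.862
```

The habitat signature generalizes to the external test cohorts while the
whole-tumor radiomics signature — whose volume-weighted aggregates cancel
the planted mid-habitat contrast — collapses to chance off the training
cohort (its 0.91 training AUC is pure overfitting, which the report's
DeLong matrices and calibration output quantify). The combined model adds
the independent cT signal to the habitat score. `rep1$delong`,
`rep1$calibration`, `rep1$dca` and `rep1$nomogram` hold the pairwise
tests, Hosmer–Lemeshow bins, decision curves and the points-based chart.

See `vignettes/habitat-radiomics-methods.Rmd` for the model, the design
decisions and what the synthetic validation does and does not establish.

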