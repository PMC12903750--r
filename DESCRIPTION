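Package: habrad
Title: Habitat Radiomics Pipeline for Tumor Subregion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for habitat radiomics: partitioning 3D tumor regions into
    spatially distinct subregions (habitats) by k-means clustering of
    voxel-level texture descriptors with Calinski-Harabasz model selection,
    extracting first-order, shape and gray-level matrix (GLCM, GLRLM, GLSZM)
    features per habitat, harmonizing multi-center feature tables with ComBat,
    selecting features by cross-validated LASSO inside nested cross-validation,
    training classifiers (SVM, random forest, extra-trees, gradient boosting,
    logistic), and evaluating them with DeLong-compared ROC curves,
    Hosmer-Lemeshow calibration, decision-curve analysis and a points-based
    nomogram. Includes a synthetic multi-center phantom cohort generator with
    planted habitat structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    e1071,
    ranger,
    xgboost,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
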