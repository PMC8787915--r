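Package: atnprog
Title: Stratification of Cognitive Progression Phenotypes from AT(N) Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Data-driven stratification of progression along the Alzheimer's
    disease continuum. Longitudinal cognitive scores are clustered into
    moderate and fast decliner phenotypes with dynamic time warping and
    hierarchical agglomerative clustering (Ward and UPGMA linkages, silhouette
    model selection). A parameter-efficient multimodal 3D convolutional
    network (PENet) predicts the phenotype from baseline amyloid, tau and
    neurodegeneration (AT(N)) biomarkers, with stratified cross-validation,
    volume augmentation and a biomarker-combination ablation harness
    (ROC/AUC, DeLong tests, logistic and SVM baselines). Atrophy-based
    disease subtypes are derived from the hippocampal-to-cortical volume
    ratio and tested for association with the phenotypes. A synthetic-cohort
    generator with configurable biomarker effect sizes, including an
    amyloid-by-tau synergy term, makes the whole pipeline testable without
    access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    e1071,
    mclust,
    ape,
    withr,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
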