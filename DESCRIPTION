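Package: orgprofiler
Title: Image-Based Phenotype Profiling of Patient-Derived Cancer Organoids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for high-content image-based profiling of 3D
    tumour organoids: maximum-contrast projection of multi-channel z-stacks,
    intensity-based segmentation, single-organoid shape/intensity/texture
    features with median-absolute-deviation filtering and batch centering,
    incremental principal component compression, UMAP embedding with
    graph-based clustering and dose-dependent principal-curve trajectories,
    control-anchored live/dead classification and well-level viability
    scores, Loess plate normalization with Hill dose-response AUC summaries,
    logistic-regression drug-effect profiles with AUROC activity calls,
    cosine clustering of effect profiles with Fisher mechanism-of-action
    enrichment, and a multi-view latent factor model linking morphology,
    size, expression, mutations and drug activity, including projection of
    drug-induced phenotypes onto learned factors. Ships a synthetic-data
    generator emulating all required inputs so every stage is testable
    without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    uwot,
    igraph,
    FNN,
    randomForest,
    glmnet,
    mclust,
    MASS,
    minpack.lm,
    pROC,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
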