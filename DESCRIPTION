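Package: MorphoImprint
Title: Anatomical-Environment Concordance Analysis for CT Lesion Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies whether unsupervised morphological clusters of CT lesions
    align more with the lesion's anatomical environment than with its primary
    tumor type. Provides a seeded synthetic 3-D lesion-phantom generator (NRRD
    volumes, binary masks and metadata), IBSI-style radiomic feature extraction
    (shape, first-order intensity, and GLCM/GLRLM/GLSZM/NGTDM/GLDM texture
    families) with isotropic resampling and one-voxel 6-connected mask erosion,
    t-SNE embedding with objective-driven agglomerative clustering, bootstrap
    adjusted-Rand-index concordance inference, and an experiment grid covering
    lesion-class stratification, feature-class ablation and tumor-core
    (erosion) robustness runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    Rtsne,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
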