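Package: pronelung
Title: Registration-Driven Lung Volume and Movement Analysis for Prone-Supine CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how lung parenchyma redistributes between supine and
    prone positioning from paired thoracic CT volumes. Provides NIfTI domain
    types with a fixed patient-anatomy axis convention, a five-lobe digital
    thoracic phantom simulator with ground-truth pose and deformation,
    cube-grid preprocessing with attenuation scaling, classical threshold and
    morphology lung segmentation with lobar assignment, shear-free affine
    registration of lung masks, multi-resolution demons deformable
    registration yielding a dense displacement field, lobar volumetry and
    per-axis/3D movement maxima, Dice-based registration quality control,
    cohort statistics (paired and Welch t-tests, one-way ANOVA, Spearman
    correlation), and HSV/quiver visualisation of displacement fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    grDevices,
    graphics,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
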