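Package: filtrad
Title: Filtration-Histogram CT Texture Analysis with Survival Biomarker
    Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Filtration-histogram texture analysis of CT lesions:
    Laplacian-of-Gaussian band-pass filtration of axial slices at spatial
    scale filters (SSF) 0-6 mm, six first-order histogram features over a
    volumetric region of interest (mean, standard deviation, entropy,
    kurtosis, skewness, mean of positive pixels), and the prognostic
    statistics chain used to evaluate such features as survival biomarkers
    (ROC/AUC screening against progression, optimal-threshold Kaplan-Meier
    with log-rank tests, univariate Cox proportional hazards with Efron tie
    handling). Includes a synthetic cohort generator producing textured 3D
    lesion phantoms and survival outcomes whose hazard depends on the
    lesion's true mean-of-positive-pixels, so the whole pipeline is testable
    without patient data, plus NIfTI/DICOM/CSV input-output and an
    end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
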