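Package: ramrad
Title: Multimodal Raman-Spectroscopy and MRI-Radiomics Classification of
    Prostate Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for in-vivo prostate-cancer detection
    combining fibre-optic Raman spectroscopy with co-located multiparametric
    MRI radiomics. Provides replicate-spectrum preprocessing (cosmic-ray
    rejection, autofluorescence baseline removal, standard normal variate
    normalization), first-order and grey-level co-occurrence radiomics on a
    5-mm spherical region of interest in anisotropic T2/ADC/b2000 volumes,
    a leakage-safe per-fold variance/correlation/capped-lasso feature-selection
    cascade, cost-sensitive linear support-vector classification with Platt
    posterior calibration under leave-one-patient-out cross-validation, and
    drivers for feature-combination, feature-count-sweep and prediction-task
    experiments. Includes a seeded synthetic-cohort generator emulating the
    statistical structure of an 18-patient pilot study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
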