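Package: qsmrim
Title: In-Silico Validation of QSM Versus High-Pass-Filtered Phase for
    Paramagnetic Rim Lesion Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates multiple-sclerosis lesion susceptibility phantoms,
    synthesizes multi-echo gradient-echo MRI data through the k-space dipole
    forward model, reconstructs both high-pass-filtered (HPF) phase images and
    quantitative susceptibility maps (QSM), scores paramagnetic-rim positivity
    on each modality against known iron-rim ground truth, and computes the
    diagnostic-accuracy (sensitivity, specificity, PPV, NPV, accuracy) and
    rater-agreement (Fleiss and Cohen kappa) statistics used to compare the
    two modalities.  The pipeline demonstrates mechanistically why HPF phase
    imaging produces false-positive rims on solid (iron-negative) lesions
    while dipole inversion does not.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
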