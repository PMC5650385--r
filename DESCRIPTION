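Package: radprog
Title: Radiomics Prognostic Signatures from Segmented MRI Tumor Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and validates radiomics-based prognostic signatures for
    progression-free survival from co-registered, segmented 3D MRI tumor
    volumes. Provides Laplacian-of-Gaussian and undecimated wavelet image
    variants, gray-level co-occurrence and run-length texture matrices,
    first-order and shape features (a deterministic 485-feature catalog per
    sequence, 970 per patient), lasso-penalized Cox feature selection with a
    linear Rad-score and median risk dichotomization, multivariate Cox models
    with and without the signature, Kaplan-Meier estimation with log-rank
    tests and clinical subgroup stratification, and a seeded synthetic cohort
    generator with planted prognostic texture signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    glmnet,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
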