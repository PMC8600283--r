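Package: eigenbrains
Title: Eigenbrain Decomposition and Clinical Decoding of FDG-PET Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Decomposes inter-individual covariance of co-registered volumetric
    FDG-PET uptake images into voxel-space eigenvectors ("eigenbrains") with
    per-participant weights, following the between-subject variability
    projection and reduction (BPR) approach: voxel-wise standardization,
    subject-wise centring, eigen-decomposition of the participant-by-participant
    covariance via the eigenfaces identity, and projection of new scans into the
    latent space. Clinical and demographic variables are then decoded from the
    standardized weights with linear and logistic regressions, omnibus tests and
    Benjamini-Hochberg false discovery rate control. Includes reference-region
    intensity normalization and Gaussian smoothing of NIfTI volumes, cohort
    description statistics (prevalence, median/IQR, normative-score conversion,
    SUVR positivity), and a synthetic phantom-cohort generator with planted
    spatial patterns and clinical links for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
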