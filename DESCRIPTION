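Package: dimorphMVPA
Title: Searchlight Multivariate Pattern Analysis of Sex Differences in
    Gray-Matter Morphometry and Autism Symptom Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying sexual dimorphism in symptom profiles and
    brain structure: domain-wise statistics and sparse (L1-penalized)
    classification of symptom tables, voxel-based-morphometry style
    mass-univariate group statistics on gray-matter volume images,
    searchlight multivariate pattern analysis with grid-searched RBF
    support-vector machines, binomial inference on cross-validation
    accuracy with Monte-Carlo cluster-extent correction, sphere-ROI
    support-vector regression linking morphometry to symptom severity
    with permutation nulls and FDR control, and a synthetic-cohort
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    glmnet,
    car,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
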