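Package: svrlsm
Title: Multivariate Lesion-Symptom Mapping by Support Vector Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate lesion-symptom mapping for stroke cohorts using
    epsilon-insensitive support vector regression with a radial basis
    function kernel. Provides psychometric scoring of working-memory span
    tasks (linear interpolation at a 75% accuracy criterion) and
    picture-word matching d-prime measures, covariate residualization and
    min-max scaling of dependent variables, construction of the subjects by
    voxels lesion matrix with a minimum-coverage filter and lossless patch
    compression, permutation-ranked hyperparameter selection by
    cross-validated error, per-patch permutation inference on
    back-projected beta maps, atlas-based region summaries, and a seeded
    simulator of lesion-deficit cohorts for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
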