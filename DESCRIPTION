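Package: lesionstab
Title: Stability of Univariate and Multivariate Lesion-Deficit Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ground-truth simulation framework for lesion-symptom mapping.
    Generates synthetic stroke-lesion cohorts with territory-structured
    multicollinearity, extracts atlas-based region lesion loads, simulates
    deficits with calibrated normal noise, and maps lesion-deficit
    relationships with mass-univariate Pearson correlation (Bonferroni
    family-wise control) and L1-penalized regression with cross-validated
    penalty selection. A subsampling pipeline repeats the mapping on random
    subsamples and quantifies the stability, sensitivity and specificity of
    each method's selected regions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
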