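Package: adps
Title: AD Pattern Similarity Scores from High-Dimensional Regularized Logistic Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes AD Pattern Similarity (AD-PS) scores: class-conditional
    probabilities from elastic-net regularized logistic regression fitted
    directly on voxel-level brain tissue maps (grey matter, white matter,
    cerebrospinal fluid) or cognitive test batteries. Provides a coordinate
    descent solver for high-dimensional penalized logistic regression, a
    nested (three-way split) cross-validation protocol with grid search for
    unbiased performance estimation and out-of-fold scoring, stability-ratio
    discriminative maps written back into masked volume space, probability
    hypercube composite risk metrics with risk-zone classification,
    Kolmogorov-Smirnov group comparisons, proportional-hazards association of
    scores with conversion times, and a synthetic multi-group cohort generator
    with planted atrophy effects for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
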