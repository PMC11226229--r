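Package: factorgeom
Title: Factorization and Invariance Metrics for Neural Population Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how a neural population (or an artificial network
    layer) organises variance driven by different scene parameters.  Provides
    PCA-based and covariance-based factorization scores, invariance
    (tolerance) scores, effective-dimensionality measures, a rotation
    "lesion" that selectively destroys factorization while conserving all
    within-class statistics, permutation null distributions, regularized
    linear decoders, ridge encoding fits, representational-similarity and
    behavioral-signature comparisons, and a meta-analysis layer that
    correlates geometry metrics with data predictivity across a library of
    models.  Synthetic-data generators with known ground-truth geometry
    support validation of every metric by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
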