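Package: isgtkit
Title: Scoring and Spatial Proximity Analysis of Interferon-Stimulated
    Gene Expressing T Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying interferon-stimulated gene expressing T
    (ISG-T) cells in single-cell and imaging-based spatial transcriptomics
    data and for quantifying their tissue neighbourhood. Implements
    per-cell gene-program scoring with expression-bin-matched random
    control genes, QC filtering and log-normalization in the two dialects
    used for sequencing-based and imaging-based spatial data,
    reference-based cell typing by cross-validated multinomial ridge
    logistic regression, score-threshold ISG-T calling with per-sample
    frequencies, and per-sample nearest-focal-cell distance analysis with
    median-distance networks, lineage-wise neighbour ranking and condition
    comparisons (one-way ANOVA with Tukey HSD, rank-sum, Welch t, Pearson).
    Includes negative-binomial expression and clustered (parent-offspring)
    tissue simulators with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
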