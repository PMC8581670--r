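Package: scnet
Title: Structural Covariance Network Analysis of Regional Cortical Thickness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares group-level structural covariance networks
    from regional cortical-thickness tables. Covariate effects (age, sex,
    overall mean thickness) are removed by ordinary least squares, Pearson
    correlation matrices are computed per group, sparsified and binarized at a
    fixed edge density, and characterized by global and local efficiency,
    normalization against degree-preserving rewired null networks, and nodal
    degree. Group differences are tested with group-reallocation permutation
    tests (percentile critical values, one-tailed p-values) and
    Benjamini-Hochberg correction across regions. Includes ANCOVA with
    post-hoc t-tests on global surface morphometry, Spearman rank correlation
    of morphological features with clinical scores, and a synthetic multi-group
    cohort generator with planted covariance topology for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
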