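Package: duplexnet
Title: Signed Two-Layer Functional Connectome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of signed functional connectomes as two-layer networks.
    Splits correlation-based connectivity matrices into layers of positive and
    negative connections, applies sign-preserving proportional thresholding
    over a density grid with area-under-curve integration, and computes
    weighted single-layer (global efficiency, clustering coefficient),
    multiplex (participation and clustering coefficients), and multilayer
    (opposite-layer minus same-layer efficiency and clustering, over a grid of
    interlayer coupling strengths) network measures. Includes a synthetic
    cross-sectional cohort generator with sex- and age-dependent connectivity
    structure, and the group-comparison workflow used with such cohorts:
    permutation tests with Benjamini-Hochberg false discovery rate control,
    polynomial age-by-sex models with exhaustive AIC subset selection, partial
    least squares regression with variable-importance-in-projection scores,
    intraclass correlation test-retest reliability, and subsample
    reproducibility analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
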