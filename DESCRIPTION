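Package: polcoherence
Title: Polarization-Coherence Analysis of Single-Cell Macrophage Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for testing whether mixed macrophage
    polarization signatures in single-cell RNA-seq arise from an admixture
    of distinctly polarized cells or from individual cells in mixed
    activation states. Provides cell-level QC filtering on sequencing
    depth and mapping rate, threshold-based marker positivity and
    detectability summaries, pairwise marker coherence statistics (linear
    regression r-squared, positivity-split Mann-Whitney tests),
    combinatorial co-expression state counting across polarization
    classes, within-gene permutation nulls for co-occurrence and for PCA
    population structure, and a seeded synthetic-data generator that
    emulates the competing population hypotheses with lognormal marker
    expression and dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
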