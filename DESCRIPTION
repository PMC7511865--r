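Package: anchorCoex
Title: Frequent Anchor-Gene Co-Expression Screening Across Expression
    Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens for candidate disease genes by their recurrent
    co-expression with a set of known "anchor" disease genes across many
    independent expression datasets. Within each dataset every gene is
    correlated (Pearson) against each anchor; a (gene, anchor) pair gains one
    unit of cross-dataset support per dataset in which the correlation passes
    a threshold, and genes correlated with at least A anchors in at least D
    datasets are nominated as candidates, ranked by their anchor count N.
    Includes readers for the GEO series-matrix dialect and plain TSV,
    probe-to-symbol collapsing, a synthetic multi-dataset generator with
    planted co-expression structure for validation, and recovery and null
    calibration metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, Microarray, Network, DifferentialExpression
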