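Package: lungage
Title: Cell-Type-Resolved Transcriptomic Aging Analysis for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparing young and aged donors in
    single-cell RNA-seq of a complex tissue. Aggregates cells to sample-level
    pseudobulk and tests each cell type with a batch-adjusted negative-binomial
    likelihood-ratio test, extracts consensus up- and downregulated aging
    signatures from genes shared by two or more cell types, computes
    control-gene-subtracted module and senescence scores per cell, and trains
    a random-forest age-state classifier with stratified splits and repeated
    cross-validation. Includes a negative-binomial scRNA-seq count simulator
    with planted differential expression and senescence effects for
    ground-truth validation, and readers/writers for MTX bundles and GMT gene
    sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    randomForest,
    stats,
    utils
Suggests:
    DESeq2,
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
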