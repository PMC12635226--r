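Package: agecrosstalk
Title: Differential Ligand-Receptor Crosstalk in Aging Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores ligand-receptor mediated cell-cell communication in
    single-cell RNA-seq data with two condition groups (young and old) and
    tests, by permuting age-group labels within each cell subset, whether an
    interaction is significantly up-regulated in one age group. The
    interaction score for a ligand-receptor pair is the product of the mean
    ligand expression in the sender cell subset and the mean receptor
    expression in the receiver subset, per age group; the permutation
    p-value is the fraction of permuted scores at least as large as the
    observed one. Also provides the standard upstream steps at the
    thresholds used in aging thymus studies: cell- and gene-level quality
    control (genes detected per cell, mitochondrial fraction, cells per
    gene), Wilcoxon rank-sum marker detection with Bonferroni correction,
    aging-associated gene detection with Benjamini-Hochberg correction, and
    a negative-binomial synthetic-data generator with planted effects for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
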