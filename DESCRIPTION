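Package: apcadeg
Title: Asymmetric Principal Component Analysis for Differential Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies differentially expressed genes from two-class
    expression matrices with unbalanced group sizes using asymmetric
    principal component analysis (APCA).  The class-conditional covariance
    matrices of the samples are weighted unequally and the between-class
    scatter is weighted heavily, so that the second principal component
    becomes a discriminant axis even when one class has far fewer samples.
    Includes a Gram-matrix (snapshot) eigendecomposition for wide matrices,
    discriminant-PC gene scoring with a half-range calling threshold,
    parameter selection by linear separability of the first two factor
    loadings, within-class Pearson correlation networks over the called
    genes, Mann-Whitney ROC/AUC evaluation of single genes and
    network-derived gene combinations, a reader for GEO series-matrix and
    plain TSV expression tables with exact duplicate-sample collapsing, and
    a synthetic data generator with planted differential genes for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
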