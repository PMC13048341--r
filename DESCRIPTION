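Package: pcasketch
Title: Fast Truncated and Randomized Singular Value Decomposition for Omics Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for principal component analysis of large expression
    matrices from single-cell and spatial transcriptomics. Reads sparse
    (Matrix Market) and dense (delimited) matrices, prepares them
    (orientation, log transform, centering, scaling), computes exact or
    randomized truncated singular value decompositions over a pluggable
    numeric backend, derives principal-component scores, and provides the
    validation statistics used to judge truncated decompositions against
    the exact reference: sum-of-squares-error ratio, Lin's concordance
    correlation coefficient, and Frobenius reconstruction error. Includes
    a synthetic-data generator producing low-rank matrices with known
    spectra and realistic negative-binomial count matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
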