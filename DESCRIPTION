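Package: bitclust
Title: Fast Biclustering of Binary Matrices via Bit-Pattern Templates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates maximal all-ones biclusters from binary matrices using a
    nibble (4-bit) encoding of rows, a precomputed submask lookup table, and
    pairwise bitwise-AND seed templates, with early-exit row inclusion tests.
    Includes evaluation metrics (Jaccard-based match score, bicluster relevance
    and module recovery), synthetic benchmark generators with implanted
    ground-truth biclusters, brute-force reference oracles for validation,
    expression-matrix binarization (threshold, quantile, and a simplified
    censored Gaussian-mixture method), file readers and writers for CSV/TSV,
    Matrix Market and edge-list inputs, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
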