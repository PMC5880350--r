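Package: bibitr
Title: Bit-Pattern Biclustering of Binary Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive enumeration of all-ones submatrices (biclusters) in
    binary data matrices using the BiBit bit-pattern approach: candidate
    biclusters are seeded from the bitwise AND of every pair of rows,
    deduplicated by pattern, completed with every row containing the
    pattern, and filtered by user-specified minimum row and column counts.
    Includes binarization of real-valued matrices (single threshold and a
    multi-level discretization scheme), word-packed pattern evaluation with
    32- or 64-bit words, a multithreaded execution mode guaranteed to
    reproduce serial output exactly, ARFF and delimited-text input, a
    seeded synthetic-data generator with implanted biclusters, and a naive
    reference enumerator for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    foreign,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
SystemRequirements: C++11
RoxygenNote: 7.3.3
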