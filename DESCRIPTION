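Package: clonedisp
Title: Dispersal Scores for Fluorescently Barcoded Clonal Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies spatial intermingling of barcoded tumor
    subpopulations with a Dispersal Score: the inverse of the
    across-population mean of per-population mean minimum
    cross-population distances, computed cell-wise (Euclidean or
    nearest-neighbor order) from nucleus detection tables, or
    pixel-wise from multi-label section images via an exact Euclidean
    distance transform. Includes an Eden-like lattice simulator of
    clonal growth with a tunable mixing probability for validating the
    score, generators for expression matrices with planted
    dispersal-correlated genes and for two-group survival data, a
    correlation screen that derives a dispersal gene signature,
    per-sample signature Z-scoring with high/low stratification, and
    Kaplan-Meier/log-rank survival comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    png,
    stats,
    survival,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
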