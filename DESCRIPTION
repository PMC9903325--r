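Package: speclib
Title: Spectral Library Search for Peptide Identification with Decoy
    Library Generation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A spectral library search engine for peptide identification
    from tandem mass spectrometry data. Query spectra (MGF) are matched
    against annotated spectral libraries (NIST-style MSP) using a composite
    score that combines three match p-values (cumulative binomial on peak
    mass matches, exact Kendall-Tau rank correlation of peak intensity
    ranks, and hypergeometric rank coincidence) via Fisher's method with a
    quantitative score based on the fraction of matched fragment ion
    intensity. Includes an iterative expert-system annotator for library
    spectra, a shuffle-and-reposition decoy library generator for
    target-decoy false discovery rate estimation, synthetic-pool FDR
    validation, and a synthetic data generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
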