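Package: cnvconcord
Title: Concordance of Copy-Number Variant Calls from Paired Blood and
    Buccal SNP-Array Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the quality of copy-number variant (CNV)
    calls derived from SNP genotyping arrays when the same subjects provide
    DNA from two tissues (whole blood and buccal brush swabs). Provides a
    synthetic cohort generator that emulates paired-tissue, mother-infant
    dyad structured array data (log R ratios, B allele frequencies,
    genotypes with GenCall-like quality scores); exact penalized
    change-point segmentation of log R ratio series with segment-mean
    projection; a distance-dependent hidden Markov model CNV caller with
    log10 Bayes-factor filtering; stratified pairwise Pearson concordance
    of raw and segment-mean series (self, mother-child, unrelated pairs);
    SNP call-rate, concordance, and Mendelian duo consistency QC with
    sample-swap detection; and Table-style CNV count and size summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
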