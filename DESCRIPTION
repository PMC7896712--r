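Package: idbench
Title: Benchmarking Genomic Inbreeding Coefficients as Estimators of
    Inbreeding Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-time individual-based simulation of a Wright-Fisher
    monoecious population with pleiotropic deleterious mutations, and a
    complete analysis pipeline to benchmark genomic measures of the
    inbreeding coefficient as estimators of the rate of inbreeding
    depression.  Implements the SNP-by-SNP estimators F^I, F^II, F^III
    (GCTA's Fhat1-3) and F_HOM (PLINK --het), LD pruning and PLINK-style
    runs-of-homozygosity detection (F_ROH at configurable length
    thresholds), homozygous mutation load metrics, the true inbreeding
    load from segregating trait loci (sum of 2dpq), regression-based
    estimation of inbreeding depression, and replicate-level evaluation
    (bias, RMSE, correlation matrices).  PLINK PED/MAP text files are
    supported as the marker exchange format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
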