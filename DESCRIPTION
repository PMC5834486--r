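Package: triadscan
Title: Gene-Environment Interaction Scans in Case-Parent Triad Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Family-based association analysis for case-parent triads and
    parent-child dyads. Implements the retrospective log-linear relative-risk
    likelihood for single-SNP and multi-SNP haplotype windows with maximum
    likelihood reconstruction of unobserved phase and missing parental
    genotypes, exposure-stratified fits with a Wald relative-risk-ratio test
    for gene-environment interaction, genome-wide sliding-window scans,
    Storey-Tibshirani q-values, QQ and Manhattan plot tables, asymptotic power
    calculations for the interaction test, and a synthetic triad study
    generator for validation. Pedigree data are read from whitespace-delimited
    PED/MAP text files.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
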