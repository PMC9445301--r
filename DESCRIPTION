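Package: burstmosaic
Title: Transcriptional Bursting, Allelic Imbalance and Contractile
    Heterogeneity in Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation of burst-like, allele-independent
    transcription (two-state telegraph model with mRNA and protein
    turnover) in cardiomyocytes, and the downstream quantification
    chain used to study cell-to-cell allelic imbalance in heterozygous
    hypertrophic cardiomyopathy: active-transcription-site (aTS)
    distributions, mRNA copy-number dispersion, densitometric
    allele-specific restriction and western-blot quantification with
    replicate quality control, qPCR absolute and relative
    quantification, force-pCa Hill and two-segment logit fitting, and
    variance-heterogeneity comparisons, together with a seeded
    synthetic-data generator so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    mclust,
    multcomp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
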