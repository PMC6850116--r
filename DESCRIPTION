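Package: ddmosaic
Title: Mosaicism Detection from Droplet Digital PCR and Deep Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying low-fraction genetic
    mosaicism from micro-droplet digital PCR (mDDPCR) and deep amplicon
    sequencing assays. Provides exact binomial (Clopper-Pearson) confidence
    intervals for mutant allele fractions (MAF), a CI-based positive-detection
    rule for mosaic calls, negative-control error-rate pooling with
    detection-limit curves, cross-platform concordance, hierarchical
    clustering of square-root-transformed multi-tissue MAFs with Newick
    export, family-level inheritance classification, and cohort summaries.
    Includes a synthetic-data generator for droplet assays, amplicon read
    counts, and whole family cohorts, plus bundled reference tables from a
    published ATP1A3 alternating-hemiplegia-of-childhood mosaicism screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
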