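Package: cellauth
Title: SNP and STR Identity Scoring for Human Cell Line Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for authenticating human cell lines and biosamples from
    SNP fingerprinting panels and STR profiles. Computes pairwise
    allele-sharing (Tanabe) identity scores over arbitrary marker subsets,
    fits Gaussian reference distributions to score classes and reports
    relatedness tail probabilities, calls sample sex independently from
    allosome SNPs, STR amelogenin and array-derived chromosome X/Y features,
    simulates and detects in-silico cross-contamination as copy-number
    weighted genotype mixtures, and generates fully synthetic populations
    (replicates, same-patient derivatives, microsatellite instability,
    chromosome Y loss, aneuploidy) so that every stage of the pipeline can
    be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
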