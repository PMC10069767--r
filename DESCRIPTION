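Package: mkduet
Title: Deconvolution of a Concealed Male-Killing Wolbachia Co-Infection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting a male-killing (MK) Wolbachia strain hidden
    behind a co-resident cytoplasmic-incompatibility (CI) strain and a dominant
    host suppressor. Implements normalized sliding-window read-depth analysis
    with segmentation and copy-number versus strain-private classification of
    depressed regions, relative strain titer estimation with bootstrap
    intervals, strain assignment of candidate loci (wmk, cifA/B, WO prophage
    recombinases) from homolog hit tables, heterozygosity and F_IS contrasts
    with selective-sweep interval detection from backcross SNP panels, and a
    generative inheritance model of CI, late-acting MK, imperfect maternal
    transmission and dominant nuclear suppression, with deterministic cross
    expectations and stochastic vial-population simulation. Synthetic-data
    generators reproduce the statistical structure of two-strain mixture
    sequencing coverage and suppressor backcross genotypes so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    Biostrings,
    vcfR
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
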