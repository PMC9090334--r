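Package: sdrscreen
Title: Forward Genetics and Chemoproteomics Analysis of SDR-Activated
    Alkynylcarbinol Prodrugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for identifying short-chain
    dehydrogenase/reductase (SDR) enzymes that bioactivate alkynylcarbinol
    prodrugs into protein-reactive alkynylketones. Implements the
    forward-genetics inference used on EMS-mutagenized pseudo-haploid
    resistant clones (clone-specific variant filtering, cross-clone gene
    recurrence, expression-silencing detection, full-coverage candidate
    nomination), exact-mass arithmetic for ynone probes and their Michael
    adducts (formula parsing, monoisotopic masses, isoDTB heavy/light
    offsets, adduct stoichiometry on deconvoluted intact-protein masses),
    label-free pull-down enrichment statistics with modified-residue
    sequence-context analysis, four-parameter logistic dose-response
    fitting with fold-resistance, and seeded synthetic-data generators
    that emulate each input with machine-readable ground truth.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
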