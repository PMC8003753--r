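Package: lantiscan
Title: Genome Mining of Lantibiotic Resistance Operons and Nisin
    Susceptibility Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An in-silico survey toolkit for lantibiotic (e.g. nisin)
    resistance traits in bacterial genomes, built around the unusual
    extracellular-domain-less BceAB-like transporter/kinase systems of
    Corynebacterium. Provides exact affine-gap protein homology search
    with Karlin-Altschul E-values, sequence-signature domain calling,
    distance-based operon assembly and architecture classification,
    sliding-window transmembrane topology prediction with
    positive-inside orientation, rule-based bacteriocin gene cluster
    detection and class assignment, 16S neighbor-joining phylogenies
    with bootstrap support, and microdilution MIC / Gompertz
    dose-response analysis. A seed-deterministic synthetic-data module
    generates genomes with planted operons, membrane proteins with
    prescribed topology, alignments evolved along known trees, and
    noisy dilution plates, so every stage is verifiable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    phangorn,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
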