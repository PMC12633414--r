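Package: aqerscan
Title: Detection of Rapidly Evolved Genomic Regions from Probabilistic
    Ancestral Reconstructions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies ancestor quickly evolved regions (AQERs) -- the most
    rapidly diverged windows of a genome between two internal nodes of a
    fixed phylogeny -- from multiple sequence alignments of complete great
    ape assemblies.  Reconstructs ancestral sequences as per-site posterior
    base-probability vectors under a Jukes-Cantor model (Felsenstein
    pruning), fits neutral branch lengths from fourfold degenerate sites,
    scans sliding windows for elevated substitution and gap-event counts
    with conservative binomial/Benjamini-Hochberg significance, and supplies
    the downstream statistics used to characterise such regions: fixed
    versus polymorphic divergent-site partitions, derived allele frequency
    spectra with proximity blocking, reversion-candidate classification,
    interval overlap enrichment with a Poisson-binomial placement null, and
    single-cell STARR-seq enhancer activity scoring against a gamma null.
    Includes seeded generators for synthetic alignments, population variants
    under a scaled selection parameter, and reporter count matrices, so the
    whole pipeline runs and is validated without external data.
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
    IRanges,
    MASS,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    phangorn,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
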