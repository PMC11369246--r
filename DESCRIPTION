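Package: satmine
Title: Satellite DNA Discovery, Quantification and Haplotype Networks from Unassembled Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the satellitome of a genome directly from raw
    paired-end sequencing reads: iterative de novo discovery of tandem-repeat
    monomers from k-mer de Bruijn graph cycles, catalog construction with
    rotation- and strand-aware canonical forms, single-linkage grouping of
    monomers into variants, families and superfamilies by sequence identity,
    per-sex abundance estimation by read masking, Kimura two-parameter
    divergence landscapes, male/female abundance-ratio calls for sex-linked
    repeats, and minimum-spanning-tree haplotype networks of short monomers.
    Includes a paired-end read simulator that plants tandem satellite arrays
    (including Y-linked arrays) with exactly known ground truth, so the whole
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
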