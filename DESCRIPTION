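Package: crossmeth
Title: Cross-Species Methylation Array Analysis with 5-hmC Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for repurposing human Infinium-style DNA methylation
    arrays in non-human mammals and for dual-aliquot quantification of
    5-hydroxymethylcytosine (5-hmC). Identifies species-competent probes by
    mismatch-bounded scanning of 50-mer probe sequences against a target
    genome, processes methylated/unmethylated signal intensities into
    quality-controlled beta values, pairs bisulfite-only and Tet-assisted
    bisulfite (TAB) aliquots to separate 5-mC from 5-hmC, tests per-CpG
    differential methylation with a BeadChip random effect and permutation
    validation, and assesses genomic-context enrichment (CpG island
    relations, gene structure, chromosomes) by Fisher's exact test and
    permutation. Includes a synthetic-data generator (toy genomes, diverged
    species genomes, probe manifests, dual-aliquot intensity matrices with
    known ground truth) so the full pipeline can be exercised end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    nlme,
    limma,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    withr,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
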