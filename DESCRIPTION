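Package: cipkfam
Title: Genome-Wide Characterization of Domain-Defined Kinase Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide characterization of gene
    families defined by domain co-occurrence, modelled on the CBL-interacting
    protein kinase (CIPK) family of soybean. Identifies family members by
    requiring both a protein-kinase and a NAF domain hit, computes per-protein
    molecular weight and isoelectric point, counts exons and introns from gene
    models and classifies genes into intron-poor and intron-rich clades,
    builds neighbor-joining trees with bootstrap supports from
    Poisson-corrected pairwise-deletion distances, detects tandem arrays and
    segmental-duplication pairs, and quantifies drought expression responses
    from microarray log-ratios and qRT-PCR cycle thresholds by the
    2^-delta-delta-Ct method. Ships a synthetic-data generator that plants
    known family members, decoys, tandem clusters, segmental blocks, intron
    structures and expression fold changes so every stage is testable without
    genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
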