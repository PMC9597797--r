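Package: dloopkin
Title: Breed Kinship and Maternal Structure from Mitochondrial D-Loop Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for breed-labeled mitochondrial control-region
    (D-loop) haplotype alignments, as used to trace maternal lineages in
    livestock. Reads FASTA alignments and breed metadata, applies
    database-assembly and column-quality filters (end trimming, conserved-block
    masking, missing-data locus removal), assigns sequences to deep maternal
    haplogroups by their placement in a phylogenetic tree, counts type-1
    (strict sister) and type-2 (tip sister to a cherry) phylogenetic
    connections between breeds, computes pairwise Phi-ST by analysis of
    molecular variance on pairwise sequence differences, and summarizes breed
    affinities by non-metric multidimensional scaling and average-linkage
    clustering. A structured-coalescent simulator with optional introgression
    pulses generates test datasets with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    vegan,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
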