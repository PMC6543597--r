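Package: repeatscape
Title: Repeat Landscape Characterization from Unassembled Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale characterization of the repetitive fraction of large
    plant genomes directly from unassembled whole-genome shotgun reads,
    modelled on the workflow used for allohexaploid oat (Avena sativa,
    AACCDD). Provides a truth-annotated synthetic genome and paired-end read
    simulator for multi-subgenome genomes carrying planted repeat families
    (LTR retrotransposons, satellites with higher-order repeat structure,
    rDNA units, DNA transposons); canonical k-mer spectra and cumulative
    genome-repetitivity curves; graph-based read clustering into repeat
    families under an overlap-identity edge criterion; domain-order
    superfamily annotation (Gypsy RT-RH-INT vs Copia INT-RT-RH) and
    cluster-graph shape classification; tandem-repeat monomer and
    higher-order-repeat detection via lag-identity periodicity profiles;
    and per-subgenome copy-number estimation with five-category
    genome-specificity calls.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
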