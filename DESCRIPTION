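Package: TEpopgen
Title: Population Genomics of Transposable Element Insertions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing transposable element (TE) insertion
    polymorphism across a cohort of assembled genomes. Per-strain TE
    annotations are transferred to a common reference genome by flank
    similarity and gene-synteny anchoring, clustered into orthologous
    insertion loci, and classified by population frequency with
    rarefaction over genome counts. Extended haplotype homozygosity
    statistics (iHS, nSL, iHH12) are computed from phased SNP panels,
    normalised in frequency bins, and calibrated against neutrally
    evolving short-intron sites to screen insertions for linkage to
    incomplete selective sweeps. TE presence/absence genotypes are
    associated with nearby gene expression through a permutation-based
    cis-eQTL pass with a beta-distribution approximation for
    multiple-testing adjustment. A synthetic-cohort generator with a
    full truth table makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
biocViews: Genetics, PopulationGenetics, StructuralVariation,
    Transcriptomics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
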