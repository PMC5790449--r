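Package: sncensus
Title: Small RNA Census Across Biospecimens
Version: 0.1.0
Authors@R: person("sncensus", "authors", email = "sncensus@example.org", role = c("aut", "cre"))
Description: A two-phase small RNA-seq quantification and census pipeline for
    comparing the small non-coding RNA content of different biospecimens
    (plasma exosomes, stool, urine, cervical scrapes). Phase one aligns
    adapter-trimmed reads to precursor miRNA hairpins with a mismatch cap and
    builds a mature-miRNA counting matrix with isomiR calling; phase two maps
    the miRNA-unmapped reads to the genome and quantifies size-selected
    non-miRNA small RNA annotations (piRNA, tRNA, short GENCODE-class loci)
    with shared counting of homologous identical-sequence loci. Downstream
    stages provide median-of-ratios library size factors, batch median
    centering for multi-study groups, a detection census with Venn
    decomposition into common and specimen-specific sets, MAD/median
    reference-RNA stability ranking, paired-subject cross-specimen
    correlation, and random-forest specimen classification with chi-square
    attribute ranking. A fully seeded synthetic cohort generator with planted
    ground truth drives the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    data.table,
    matrixStats,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
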