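Package: snrand
Title: Simulation, Demultiplexing, Quantification and QC for Pre-Indexed
    Random-Primed Droplet Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational layer of pre-indexed, random-primed
    droplet single-nucleus total RNA sequencing chemistries (snRandom-seq
    style libraries). Provides a generative simulator of paired-end read
    libraries with full per-read ground truth (two-species barnyard mixtures,
    Poisson droplet co-encapsulation, split-pool bead barcodes, pre-index RT
    tubes, dA-tail junctions, intron-rich random priming), together with the
    matching processing steps: barcode/UMI extraction and Hamming-bounded
    whitelist correction, read trimming and demultiplexing, gene and region
    assignment with directional UMI deduplication into spliced/unspliced
    count matrices, barcode-rank knee calling, and the validation metrics
    used to qualify such libraries (species-mixing doublet rates, gene-body
    coverage, sequencing saturation, biotype tallies, matrix filtering and
    pseudobulk replicate correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
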