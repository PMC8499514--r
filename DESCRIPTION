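Package: vistrackr
Title: Quantitative Clonal Tracking of Lentiviral Vector Integration Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative, longitudinal clonal tracking of
    lentiviral vector integration sites (VIS) from LTR-junction sequencing
    reads. Covers the full workflow: LTR-anchor detection and LTR-index
    demultiplexing of junction reads, two-pass mapping of host junction
    segments onto a reference genome, aggregation into a VIS-by-sample
    count matrix with signal-crossover and cross-animal collision
    correction, clone frequency estimation, longitudinal clone analytics
    (frequency bands, persistence, top clones, sharing, replicate
    concordance via Pearson correlation and the absolute-agreement
    intraclass correlation), Renyi diversity profiles, a restriction-motif
    constrained random integration-site null model, genomic and epigenomic
    annotation of integration sites (nearest gene, expression activity,
    chromatin-feature peak distances, coverage matrices), and a synthetic
    data generator that emulates the full assay with known clonal truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
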