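Package: bscapture
Title: Simulation and Analysis of Targeted Capture Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully tested implementation of the computational
    workflow behind liquid hybridization capture bisulfite sequencing:
    simulation of captured bisulfite-converted paired-end libraries from a
    known truth methylome (capture enrichment, PCR duplicates, incomplete
    conversion, sequencing errors, heterozygous sites), three-letter
    bisulfite-aware alignment against C-to-T and G-to-A converted reference
    indexes with seed and mismatch limits, per-cytosine methylation calling
    with non-conversion correction estimated from non-CpG sites, capture QC
    and allele-dropout estimation, three-criterion differentially methylated
    region detection by Fisher's exact test, metagene methylation profiling,
    and replicate concordance statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
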