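Package: redoxreg
Title: Transcriptional Cluster Analysis and Pigmentation Phenotyping for a
    Photosynthesis Regulator Mutant
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparing a Rhodospirillum rubrum regulatory
    mutant against its parent strain: two-condition negative-binomial Wald
    differential expression with a signed fold-change convention,
    significance filtering with a transcriptional-cluster rescue rule,
    strand-aware transcriptional cluster calling from intergenic distances,
    fold-change profiling of named genomic regions (photosynthesis gene
    clusters) and biological-process categories, pigmentation metrics
    (photomembrane production index and its difference to an unpigmented
    control) from optical-density time series, and variant screening with
    frameshift-consequence prediction. Includes a synthetic-data generator
    with planted truth so the whole pipeline is testable without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
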