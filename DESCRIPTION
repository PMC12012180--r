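Package: spermEpi
Title: Chromatin and Methylome Analytics for Staged Spermatogenesis Epigenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analytics for stage-resolved epigenomic profiling of
    male germ cell development. Consolidates ChIP-seq peaks into broad and
    regular H3K4me3/H3K27ac domains, classifies them against promoter
    annotation, identifies ROSE-style super domains from signal-ranked
    stitched regions, tracks H3K4me3/H3K27me3 bivalent promoter states
    across the spermatogenic stage series, implements a NOMe-seq engine
    (WCG/GCH cytosine context classification, coverage-filtered methylation
    and accessibility levels, chi-square sliding-window nucleosome-depleted
    region calling, binned matrices and metagene profiles), summarises
    chromatin-state segmentation dynamics between adjacent stages, and
    classifies stage-specific expression timing together with knockout
    timing-shift signatures. A synthetic-data generator emits every input
    the pipeline consumes with ground-truth labels, so the whole analysis
    is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
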