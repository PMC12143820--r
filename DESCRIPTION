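Package: sercall
Title: Super-Enhancer Calling and ChIP-seq/RNA-seq Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-ordering super-enhancer (ROSE-style) analysis of H3K27ac
    ChIP-seq peaks: exclusion of TSS-proximal peaks, stitching of enhancers
    within a fixed genomic gap, rank ordering of stitched enhancers by signal,
    and the slope-1 tangent cutoff separating super-enhancers from typical
    enhancers. Includes genomic feature annotation of peaks (promoter, exon,
    intron, distal intergenic), a two-condition differential signal test,
    FPKM-based differential expression screening, nearest-gene integration of
    differential super-enhancers with expression changes, a seeded synthetic
    two-condition landscape generator with ground truth for benchmarking, and
    small bench-assay helpers (2^-ddCt, dual-luciferase, ChIP-qPCR enrichment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
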