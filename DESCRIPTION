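Package: dmvscape
Title: DNA Methylation Valley Discovery and Regulatory Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies DNA methylation valleys (DMVs) from per-cytosine
    whole-genome bisulfite sequencing calls with a 1-kb sliding-window scan
    over the CG, CHG and CHH contexts, merges them into contiguous valley
    regions, and derives the valley set conserved across tissues. Relates
    valleys to gene annotation (genic, promoter, downstream and distal
    categories; DMV genes whose body plus 1-kb flanks lie entirely within a
    valley; nearest-gene assignment for distal valleys), scores tissue
    specificity of an FPKM expression atlas by Shannon entropy and Z-scores,
    and quantifies histone-mark peak enrichment within valleys, including
    binned meta-region profiles and chi-squared enrichment tests. A seeded
    synthetic-data module generates methylomes, expression atlases and peak
    sets with the statistical structure the analysis assumes, so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
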