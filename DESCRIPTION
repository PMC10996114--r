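Package: methylpop
Title: Population Methylome Analysis for Domestication Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of whole-genome bisulfite sequencing panels
    across wild, landrace and improved crop populations: cytosine-report
    parsing and coverage filtering, differentially methylated region (DMR)
    calling by binary segmentation with Mann-Whitney testing, sliding-window
    nucleotide diversity and Weir-Cockerham FST with joint top-decile
    selective-sweep detection, mixed-linear-model methylation QTL mapping with
    kinship correction and LD clumping, CG/CHG co-evolution and genomic
    composition analysis, and methylation-expression correlation. Includes a
    seeded synthetic-panel generator with planted DMRs, sweeps, meQTLs and
    methylation-coupled genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
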