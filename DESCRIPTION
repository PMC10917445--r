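Package: allelomap
Title: Allelic Epigenome Analysis of Uniparental Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for parent-of-origin epigenomes profiled in
    parthenogenetic (maternal-only) and androgenetic (paternal-only) embryos.
    Calls allele-specific chromatin accessibility and H3K27me3 domains,
    parental differentially methylated regions and putative germline
    imprinting control regions from per-CpG bisulfite counts, identifies
    imprinted genes by integrating allelic expression with nearby control
    regions, screens for promoters jointly repressed by maternal DNA
    methylation and paternal H3K27me3, and summarises cross-species
    conservation of allelic states over precomputed orthology maps. Ships a
    deterministic synthetic-data generator with planted ground truth so the
    whole pipeline is testable without access to restricted embryo data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
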