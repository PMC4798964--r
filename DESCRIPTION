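Package: epiconcord
Title: Methylome Segmentation and Chromatin Accessibility Concordance Analysis
Version: 0.1.0
Authors@R: person("Epiconcord", "Developers", email = "epiconcord@example.org",
    role = c("aut", "cre"))
Description: Tools for joint analysis of single-base bisulfite methylomes and
    chromatin accessibility data in closely related neuronal cell types.
    Implements hypo-methylated region segmentation (UMRs, LMRs and DNA
    methylation valleys), replicate-aware beta-binomial differential
    methylation calling with block joining into DMRs, consensus and
    differential accessibility peak classification, methylation/accessibility
    concordance statistics including detection of hypo-methylated but
    inaccessible ("vestigial") regulatory regions, epigenomic distance
    matrices with hierarchical clustering, and a linear gapped k-mer model
    for regulatory sequence scoring. A seeded synthetic-epigenome generator
    plants known regulatory region classes so that every stage of the
    pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Biostrings,
    jsonlite,
    ape,
    withr,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
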