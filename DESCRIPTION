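Package: reqtlmap
Title: Response eQTL Mapping for Paired-Condition Expression Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects cis- and trans-acting expression QTL from a genotyped
    inbred panel assayed under two conditions (e.g. control and heat stress),
    tests each gene's top cis variant for a genotype-by-condition interaction
    with a paired random-intercept mixed model (Satterthwaite degrees of
    freedom), classifies responsive genes by which allele responds and in
    which direction, detects condition-specific expressed eGenes and
    trans-eQTL hotspots, and prioritizes candidate causal variants by overlap
    with condition-enriched transcription-factor footprints. Includes a
    synthetic-cohort simulator with planted truth so every stage of the
    pipeline can be validated end to end at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmerTest,
    lme4,
    DESeq2,
    vcfR,
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
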