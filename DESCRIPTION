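Package: l1burden
Title: Polymorphic LINE-1 Insertion Burden and Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genotype-level analysis of polymorphic LINE-1 (L1) retrotransposon
    insertions in case-control cohorts. Reads mobile-element-insertion genotypes
    from VCF (MELT-style non-reference insertions and deletion-genotyped
    reference insertions), applies evidence, Hardy-Weinberg and allele-frequency
    quality filters with a full accounting ledger, computes the per-genome
    burden of retrotransposition-competent (RC) L1 alleles and its association
    with disease status via adjusted linear and threshold-scan logistic models,
    runs per-locus case-control, age-at-onset and survival scans, and performs
    an additive linear eQTL scan with FDR control plus an RC-enrichment test.
    Includes a fully reproducible synthetic cohort generator emulating the
    statistical structure of a large ALS whole-genome-sequencing consortium so
    that every stage is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    survival,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
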