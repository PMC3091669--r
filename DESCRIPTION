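Package: asepool
Title: Allele-Specific Expression from Pooled RNA Sequencing of an F2 Cross
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects allele-specific expression (ASE) from strand-specific
    cDNA sequencing of RNA pooled across an F2 intercross, and validates the
    calls against single-marker cis-eQTL. Provides SNP-aware allele counting
    with base-quality and SNP-type filters, exact binomial ASE tests with
    pool-derived null allele fractions, signed log10 binomial scores (LBP),
    gene-level aggregation with majority direction voting, confidence
    envelopes, replicate error models, excess-ASE estimation, exact binomial
    power, additive-effect marker regression with LOD scores, observed-versus-
    expected overlap enrichment between ASE and cis-eQTL, classification of
    allele-specific antisense transcription, allele-specific splicing bounds
    from junction reads, and a synthetic-data generator that emulates the
    pooled-cross study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
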