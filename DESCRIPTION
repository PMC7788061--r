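Package: slepath
Title: Pathway-Centred Case-Control Genetic Association and Patient
    Stratification for Systemic Lupus Erythematosus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gene-centred case-control analysis of targeted sequencing
    data, from single variants to immunological pathways. Provides
    single-variant and aggregate (SKAT-O-style) association testing with
    Benjamini-Hochberg FDR control, a sequential-elimination scheme for
    independent pathway signals, per-individual pathway polygenic risk
    scores with control-percentile positivity calling, hierarchical
    patient stratification with clinical group comparisons, rare and
    case-only variant cataloguing, and a configurable case-control
    cohort simulator with planted pathway effects for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    metafor,
    jsonlite,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    fgsea,
    optparse
Config/testthat/edition: 3
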