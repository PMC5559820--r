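Package: MutDomains
Title: Recurrent Somatic Mutation Analysis on Protein Domains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps somatic mutations from multi-cancer cohorts onto protein
    domain regions (sequence-defined Pfam-style and structure-defined
    CATH-style annotations), tests domains and genes for mutation counts in
    excess of a length-proportional binomial background model using
    log-space tail probabilities built on a Stirling-series log-factorial,
    and controls the family-wise error rate by Bonferroni correction across
    cancer types. Derives per-cancer candidate regions, patient coverage,
    cancer-type-specific domains and proteins, gene-set (grouped) tests, and
    Pfam/CATH region-overlap summaries. Includes a seeded synthetic-cohort
    generator with uniform background and planted enrichment so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: SomaticMutation, StatisticalMethod, MultipleComparison, Software
RoxygenNote: 7.3.3
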