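Package: ycap
Title: Chromosome-Y Copy Number, Deleterious Variant and Loss-of-Y Analysis for Two-Ancestry Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for chromosome-Y disparity analysis in a
    two-ancestry prostate-cancer cohort: multi-caller CNV consensus merging
    (breakpoint atomization, conflict removal, k-of-n concurrence, adjacent
    same-type merging), gene-level event annotation with ancestral-event
    flagging, a deleterious-variant filter cascade over predictor-annotated
    variant tables, Y-ploidy and mosaic loss-of-Y estimation from sequencing
    depth, and the cohort association layer (exact Fisher tests from the
    hypergeometric distribution, exact and corrected-normal Wilcoxon rank-sum
    tests, haplogroup clade-marker concordance). A seeded synthetic-cohort
    generator emulates the study design (two populations, haplogroup-linked
    germline CNVs, risk-enriched somatic CNVs, per-caller error models,
    depth profiles with implanted partial loss of Y) so every stage runs
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
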