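Package: nbpanel
Title: Targeted-Panel Somatic Analysis for Neuroblastoma Cohorts
Version: 0.9.0
Authors@R:
    person("Panel", "Genomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tumor-only targeted panel sequencing analysis for pediatric
    neuroblastoma cohorts: multi-caller somatic variant merging with
    strand-bias/cluster artifact removal and a two-rule germline filter
    (high-VAF with hotspot exemption, population-database and
    panel-of-normals frequency), an exon-coverage plus B-allele-frequency
    copy-number caller with grid-search tumor purity estimation, MYCN FISH
    amplification scoring, clinical actionability classification, and
    cohort statistics (alteration prevalence, Kaplan-Meier survival with
    Greenwood errors, log-rank tests, mutual-exclusivity checks). A
    synthetic cohort generator emulates the statistical structure of an
    83-gene panel study of 72 patients so that every stage is testable
    without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    SummarizedExperiment,
    utils,
    VariantAnnotation,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
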