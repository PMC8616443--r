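Package: epitrial
Title: In Silico Clinical Trials for Epitope-Based Vaccines over HLA-Genotyped Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts population-level immune response rates for epitope-based
    vaccines by scanning antigen sequences with overlapping 9-mer peptides and
    counting, for every subject of a fully HLA class I genotyped model cohort,
    the epitopes predicted to bind multiple autologous HLA alleles. Provides
    the full grid of in silico response-rate estimators (single-epitope,
    multi-epitope and multi-antigen variants at HLA thresholds 1-4), HLA
    preselection stratification, allele-frequency coverage, and the companion
    statistical battery: Pearson correlation with t-based p-values,
    perpendicular (orthogonal) trend fitting with bootstrap bands, the "n-1"
    chi-squared two-proportion test, ROC/AUC evaluation over trial-success
    thresholds, and per-position binder-frequency representativeness analyses.
    Seeded generators for genotyped populations, random antigens, promiscuous
    binding tables and noisy trial outcomes make every pipeline stage testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
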