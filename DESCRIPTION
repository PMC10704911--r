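Package: methylscreen
Title: Differential Methylation Screening and Epigenetic Biomarker
    Validation for 850K-Style Arrays
Version: 0.1.0
Authors@R:
    person("methylscreen", "developers", email = "methylscreen@example.org",
           role = c("aut", "cre"))
Description: A case-control pipeline for Illumina EPIC (850K)-style
    DNA-methylation beta-value matrices: probe quality-control filtering
    (detection P, bead counts, non-CpG, SNP/cross-reactive, sex
    chromosomes), differential-methylation-position (DMP) calling with
    Benjamini-Hochberg control and a delta-beta effect-size gate,
    genomic-context distribution and chi-square enrichment statistics,
    a three-criterion promoter biomarker screen, and clinical validation
    statistics (2^-ddCt relative expression, normality-gated group
    comparison, methylation-expression and methylation-phenotype
    correlation, ROC/AUC).  Ships a seeded synthetic 850K-like cohort
    generator with complete planted-truth bookkeeping so the whole
    pipeline is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
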