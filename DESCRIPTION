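Package: faecomir
Title: Stool miRNome Quantification and Covariate Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for faecal small RNA sequencing studies:
    mature microRNA quantification from precursor alignments using
    knowledge-based (annotated 5p/3p arm) and position-based (midpoint split)
    read assignment; questionnaire-derived cohort categorization (WHO BMI
    classes, age tertiles, smoking, sex-specific alcohol strata, coffee
    intake, and an EPIC-style physical activity index); detection and robust
    variability summaries (MAD/median coefficient of variation); covariate-
    adjusted negative-binomial Wald differential expression with
    Benjamini-Hochberg correction and dual significance/abundance calling
    filters; Spearman correlation profiling of continuous covariates; and
    miRNA-target gene-set enrichment by logistic regression. A synthetic-data
    module generates references, cohorts, counts, and alignments with planted
    effects so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
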