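Package: ipmnevo
Title: Multi-Region Genomic and Transcriptomic Evolution Analysis of
    Pancreatic Cyst Precursor Lesions
Version: 0.1.0
Authors@R:
    person("Atlas", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of multi-region sequencing of pancreatic
    precursor lesions (intraductal papillary mucinous neoplasms, IPMN) and
    co-occurring carcinoma. Harmonizes somatic variant calls from multiple
    callers with targeted rescue at driver loci, calls copy-number
    alterations by overlaying allelic-imbalance and log-ratio
    segmentations, computes arm-level aneuploidy scores, classifies
    per-patient clonal evolution as linear or branched from both SNVs and
    arm-level copy states (containment clone trees and exhaustive
    small-parsimony copy-number trees), assigns transcriptomic subtypes by
    nearest-template prediction with permutation significance, and tests
    subtype-by-copy-number associations with exact contingency tests. A
    synthetic multi-region cohort simulator with full ground truth drives
    end-to-end recovery testing without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    IRanges,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    ape,
    withr
Config/testthat/edition: 3
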