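Package: pedmeth
Title: Pan-Pediatric-Tumor DNA Methylation Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-level analysis of Illumina 450K promoter methylation across
    pediatric tumor cohorts. Establishes per-gene baseline methylation
    categories (level and variance) from multiple normal cohorts, applies
    empirical-Bayes batch adjustment on the logit scale, detects differential
    methylation between tumor types and the normal baseline with a moderated
    linear model, calls per-tumor hyper- and hypomethylation by z-score against
    the normal reference, extracts gene-level somatic mutation events from
    annotated variants and RNA fusions, and tests mutual exclusivity between
    mutation and aberrant-methylation events with a permutation null. Includes
    a synthetic-data generator that emulates the multi-cohort study design so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    sva
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    BatchEffect, Software
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'core_io.R'
    'preprocess.R'
    'categorize.R'
    'diffmeth.R'
    'aberrant.R'
    'events.R'
    'mutex.R'
    'synthetic.R'
    'pipeline.R'
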