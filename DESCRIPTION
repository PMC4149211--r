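Package: iso17q
Title: Replicate-Concordant Variant Filtering and Chromosome 17 Dosage-Aware
    Expression Analysis for Medulloblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the molecular analysis of medulloblastoma cohorts with
    isodicentric chromosome 17q. Implements stringent replicate-concordance
    filtering of amplicon-based variant calls from FFPE tumors (quality,
    mapping-quality and allele-fraction thresholds, annotation and population
    frequency filters, and a cross-replicate concordance rule), mutation-table
    summaries, chromosome 17 dosage-normalized expression analysis with a
    breakpoint partition into hemizygous and duplicated compartments and a
    Bonferroni-corrected focal-gene excess-suppression test, probe-normalized
    molecular-subgroup expression comparisons, Kaplan-Meier / log-rank survival
    stratification with a combined molecular-risk rule, and a synthetic-data
    generator that reproduces the statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
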