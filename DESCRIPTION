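Package: omicprio
Title: Multi-Omics Prioritization of Candidate Oncogenes and Tumor
    Suppressor Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores every gene in a cancer cohort as a candidate oncogene
    and/or tumor suppressor by counting activating and inactivating
    aberrations across five data types: mRNA expression, DNA copy number,
    DNA methylation, somatic mutations (a 20/20-rule classification of
    recurrent versus broadly distributed mutations) and shRNA knock-down
    viability screens.  Per-data-type calls combine paired and unpaired
    rank tests with Benjamini-Hochberg control, effect-size gates and
    expression-correlation requirements, and are aggregated into oncogene,
    tumor suppressor, overall and aberration scores per gene and cancer
    type, pathway-level averages, affected-sample fractions and
    tumor-versus-cell-line comparisons.  Includes readers for the standard
    interchange formats (TSV matrices, SEG, MAF column subset, GMT) and a
    seeded synthetic-cohort generator with planted driver genes for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
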