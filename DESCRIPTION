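Package: afddd
Title: Mapping Recessive Traits from Pooled Sequencing of Outcrossed
    Progeny by Allele-Frequency Difference and Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for bulked-segregant mapping of recessive traits in
    F1 progeny of two heterozygous (outcrossing) parents from pooled
    whole-genome sequencing. Provides exact expectations for pool
    variant-allele frequencies under all phase-resolved marker
    segregation types and one- or two-recessive-gene models, QC and
    zygosity grouping of per-pool variant tables, selection of
    informative SNVs by type-specific allele-frequency difference
    (AFDD) filters, sliding-window density scanning with z-score peak
    calling (LODz), marker segregation-distortion and phenotype
    statistics for confirmation, and a seeded forward simulator of a
    biparental cross with incomplete age-dependent penetrance and
    pooled read sampling for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
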