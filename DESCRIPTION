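Package: panelmarkers
Title: Somatic Panel Biomarkers, Mutation Landscape, Survival and
    Enrichment Analysis for Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested analysis chain for targeted-panel tumor sequencing
    cohorts: somatic-call filtering by variant allele frequency and read
    support, per-sample instability biomarkers (tumor mutational burden,
    microsatellite instability from paired tumor/normal repeat-length
    distributions, chromosomal instability from copy-number segments),
    gene-level mutation landscape with pairwise co-occurrence and mutual
    exclusivity, mutation-status group comparisons, Kaplan-Meier and Cox
    proportional-hazards survival modelling, and phenotype-permutation
    gene-set enrichment.  A synthetic-cohort generator with programmable
    mutation effects on every readout makes all stages testable and
    parameter recovery measurable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
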