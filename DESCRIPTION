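Package: cwasmeta
Title: Cross-Biobank Coding-Variant Association Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for coding-wide association studies (CWAS)
    across two population biobanks of unequal size, one drawn from a founder
    population with cohort-specific allele enrichment. Provides synthetic
    two-cohort genotype and phenotype generators with block-structured linkage
    disequilibrium, per-cohort logistic association testing with Firth
    fallback and minor-allele-count filters, fixed-effect inverse-variance
    meta-analysis with allele harmonization, a theoretical and simulated
    power model for the meta-analysis Z-score uplift conferred by
    population-enriched alleles, significance tiering with LD clumping and
    sentinel-region refinement, ICD-10 phenotype harmonization and disease
    clustering, clustered Mendelian randomization via an EM mixture with
    singleton clusters, and exact-test enrichment utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
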