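Package: rohtrace
Title: Runs of Homozygosity, Consensus Autozygosity Islands and
    Breed-Private Variant Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing selection signatures in livestock genomes from
    genotype data. Implements sliding-window detection of runs of homozygosity
    (ROH) with whole-genome-sequencing and SNP-chip parameter presets, group
    consensus ROH regions and breed-specific island refinement at base-pair
    resolution, the genomic inbreeding coefficient F_ROH, gene overlap and
    hypergeometric (Fisher/EASE) gene-set enrichment, a breed-private
    candidate-variant funnel over functional impact classes, validation
    statistics (genotype-frequency tables, two-locus co-segregation,
    autosomal-dominant consistency, imputation error rates), and a synthetic
    cohort generator that plants autozygosity tracts, private variants and a
    dominant phenotype locus with machine-readable truth files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
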