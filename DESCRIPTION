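Package: ampliqc
Title: Quality Control, Trio Accuracy and Population Genetics for
    Amplicon Panel Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted amplicon-panel resequencing of diverse,
    highly heterozygous plant germplasm. Provides panel coverage
    accounting over target regions and amplicons, a variant quality
    control cascade (site quality and quality-by-depth thresholds,
    genotype depth masking, an exact test for heterozygote excess with
    Bonferroni correction, an amplicon-level co-amplification filter and
    a missingness filter), trio-based heterozygote sensitivity and
    precision scoring against F1 hybrid controls, variant-set
    concordance, population-genetic summaries (observed heterozygosity,
    Nei gene diversities, Weir-Cockerham Fst, Fis), identity-by-state
    distances with classical multidimensional scaling, and a synthetic
    data generator with known ground truth that emulates structured
    landrace populations, inbred lines, F1 hybrids, amplicon dropout and
    paralog co-amplification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
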