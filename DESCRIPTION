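Package: citewas
Title: Causal Inference Testing of Blood DNA-Methylation Mediators of
    Genetic Disease Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative epigenome-wide analysis pipeline for
    case-control studies that asks whether blood DNA-methylation marks
    mediate genetic risk for disease. Implements methylation array quality
    control, beta/M-value transformation, empirical-Bayes batch adjustment
    and plate residualisation, reference-based deconvolution of the six
    major leukocyte subtypes by constrained projection, cell-adjusted
    epigenome-wide association (EWAS) with Storey q-values, a
    methylation-QTL scan under an additive minor-allele dosage model,
    SNP-disease association, and the Causal Inference Test (CIT) cascade
    that classifies CpG-SNP-phenotype trios as methylation-mediated.
    Includes a synthetic-cohort generator with planted mediated,
    consequential and independent causal topologies and full ground truth,
    so every stage of the cascade is verifiable without external data.
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
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    sva,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
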