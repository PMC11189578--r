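Package: margindiff
Title: Center-to-Margin Phenotypic and Genetic Differentiation in Inbred Plant Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether quantitative traits measured on panels of
    inbred plant genotypes are more differentiated among biogeographical groups
    than expected under genetic drift. Implements robust phenotype filtering
    (Hampel rule) and genotype-mean derivation from blocked greenhouse designs,
    latitude-and-ancestry group classification, broad-sense heritability by
    method-of-moments, Weir-Cockerham F_ST for inbred (haploid-coded) lines,
    trait Q_ST and a bootstrap Q_ST-in-F_ST test, a method-of-moments coancestry
    matrix with a Monte-Carlo drift test (the S statistic), polygenic top-SNP
    selection from sparse-model effect components (E = alpha + beta * delta),
    F_STQ/F_ST selection scans with cutoff sensitivity, and an
    outlier-haplotype enrichment bootstrap over 10-kb ancestry windows. A
    synthetic-data generator reproduces the two-lineage admixture, trade-off
    trait architecture, and blocked greenhouse design the analysis assumes, so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
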