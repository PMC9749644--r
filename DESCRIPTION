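Package: combsig
Title: Combinatorial Disease-Signature Mining for Case-Control Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines high-order combinations of SNP genotype states
    ("disease signatures") that are jointly over-represented in cases of a
    case-control cohort, validates them against a label-permutation null
    (the P1000 score and an empirical false-discovery-rate filter),
    identifies critical SNPs shared across validated signatures, scores
    them with cross-validated random forests, clusters signatures into
    patient communities by case co-occurrence, and maps SNPs to genes via
    a positional annotation cascade. Includes a synthetic case-control
    cohort generator with planted combinatorial signatures (including
    marginal-effect-free interactions), genotype quality control, matched
    control selection, a single-SNP association baseline, patient
    stratification statistics, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    igraph,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
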