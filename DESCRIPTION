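Package: pairqc
Title: Replicability Assessment for Expression Experiments via Co-Expressed
    Gene Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates how replicable a gene expression experiment is by
    injecting calibrated rank-based noise into individual samples and
    measuring how reliably the perturbed sample is detected through the
    disruption of tightly co-expressed ("housekeeping interaction") gene
    pairs, with an equal-sized random-pair null to flag technical artifact.
    Reports mean detection AUROCs across a grid of noise factors, Wilcoxon
    comparisons of the pair and null AUROC distributions, and an
    interpolated noise-level estimate. Also provides gene-level
    replicability statistics for replicate experiments (self-correlations,
    Fisher-z and t significance, multiple-testing adjustment, coverage
    extrapolation over sample size, self-correlation ranks, expression and
    fold-change filter summaries) and synthetic-data generators with known
    co-expression and replicability structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
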