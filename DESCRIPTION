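Package: longscreen
Title: Phylogenetic Screening of Omics Features for Association with
    Mammalian Longevity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-species screening of gene-expression and metabolite
    matrices for features whose levels track mammalian longevity traits.
    Implements phylogenetic generalized least squares under four
    trait-evolution models (independent residuals, Brownian motion,
    Pagel's lambda, Ornstein-Uhlenbeck) with maximum-likelihood model
    selection, a two-step outlier/leave-one-out robustness procedure with
    false-discovery-rate control, upstream count and metabolite
    normalization (filtering, trimmed mean of M-values scaling, quantile
    normalization, internal-standard scaling), allometric longevity
    residuals, neighbor-joining phylograms with bootstrap support, Kimura
    two-parameter distances, hypergeometric and Fisher enrichment
    statistics, permutation F-tests for group-specific slopes, probit
    LD50 estimation, and synthetic-data generators that emulate the
    statistical structure of cross-species fibroblast datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    fgsea
Config/testthat/edition: 3
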