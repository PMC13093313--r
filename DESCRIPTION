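Package: primeNet
Title: Co-Expression Network Preservation Analysis of Thermal Priming
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to detect genotype-dependent transcriptomic memory of
    early-life thermal priming in a factorial family x priming x
    temperature design. Implements negative-binomial GLM differential
    expression with likelihood-ratio and Wald tests, signed weighted gene
    co-expression networks with topological-overlap module detection and
    eigengene summaries, cross-family module-preservation permutation
    testing on seven network statistics, hub/gene-significance candidate
    triangulation with binarized subnetwork export, rank-based (delta-rank
    Mann-Whitney) and Fisher exact functional enrichment, and thermal
    tolerance phenotype scoring (Kaplan-Meier survival, LT50, G-rho family
    tests, allometric respiration correction). A synthetic-data generator
    with planted module and trait structure provides ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    survival,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
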