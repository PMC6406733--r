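Package: exprphylo
Title: Phylogenetic Clustering of Gene Expression Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Treats longitudinal expression samples as taxa and genes as
    characters to infer their relationships with phylogenetic methods.
    Provides neighbor-joining on continuous expression distances, Fitch
    parsimony and maximum likelihood under a symmetric three-state Markov
    model on expression discretized to down/constant/up relative to an
    outgroup sample, with the up/down cut-off chosen to maximize the number
    of parsimony-informative characters. Includes character-bootstrap branch
    support, hierarchical-clustering baselines and temporal-order scoring,
    extraction of genes differentiating the two major clades with
    hypergeometric gene-set enrichment and permutation-adjusted p-values,
    fold-change resistance scoring for single-dose drug-screen viability
    data, and synthetic time-course and plate-screen generators for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
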