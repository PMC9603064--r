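Package: tissueGxE
Title: Genotype-by-Tissue Interaction Analysis of Gene Expression
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how much of the variation in tissue-specific gene
    expression is attributable to genotype (gene) effects, tissue effects,
    and genotype-by-tissue interaction, borrowing the toolkit of
    multi-environment trial analysis: split-split-plot analysis of variance
    with its three error strata, AMMI (additive main effects and
    multiplicative interaction) decomposition of the doubly-centered
    interaction with Gollob F tests on interaction principal component
    axes, and GGE biplot geometry (tissue relationships, which-won-where
    sectors, mean-versus-stability projections, and ideal-point rankings).
    Includes delta-delta-Ct relative expression from qPCR cycle thresholds,
    a synthetic-data generator with planted additive effects, low-rank
    multiplicative interaction and stratified noise, and report writers
    that mirror the standard tables of the method.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'expression-data.R'
    'simulate.R'
    'ssp-anova.R'
    'ammi.R'
    'gge.R'
    'published-tables.R'
    'reporting.R'
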