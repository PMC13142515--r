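Package: pleiomap
Title: Post-GWAS Credible-Set Analysis, Pleiotropy Scoring and
    Drug-Target Genetic-Support Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale end-to-end post-GWAS analysis pipeline:
    qualification and harmonisation of studies and 95% credible sets
    (effect-size rescaling from p-values, major-ancestry minor allele
    frequencies, detection-power calculation), locus definition by three
    clumping strategies with PICS fine-mapping, colocalisation by
    credible-set overlap (CLPP and five-hypothesis posterior H4 with
    effect-direction concordance), locus-to-gene prioritisation from a
    28-feature credible-set by gene matrix with a gradient-boosted
    classifier, variant- and gene-level pleiotropy scoring with
    negative-binomial covariate models and gene-set logistic enrichment,
    and genetic-support enrichment in clinical success (Fisher odds ratio
    and relative success, stratified logistic comparisons, non-linear
    log-pleiotropy models, phase-transition probabilities with Wilson
    intervals). A seeded synthetic-cohort generator plants causal
    variants, colocalising molecular-QTL signals, pleiotropic genes and
    clinical pipelines so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
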