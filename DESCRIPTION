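Package: phenorules
Title: Semantic Association Rule Mining for Phenotype-Based Disorder Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers and ranks class association rules of the form
    {phenotype concepts} -> {disorder concept} over ontology-annotated patient
    cases. Replaces exact-match interestingness measures (support, confidence,
    lift, conviction, leverage, jaccard, cosine, correlation) with semantic
    variants computed from ontology structure, using custom exponential
    path-based similarity metrics alongside classic information-content
    measures (Resnik, Lin, Jiang-Conrath) and Wu-Palmer. Includes a constrained
    Apriori miner, a voting classifier evaluated by cross-validated top-K
    accuracy, McNemar paired-classifier testing, and a synthetic cohort
    generator with controllable sibling-substitution noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
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
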