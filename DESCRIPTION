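Package: moltpath
Title: Phylogenetic Comparative Analysis of Molt Evolution and Seasonal
    Dichromatism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing multi-step evolutionary hypotheses about
    biannual molt and seasonal plumage dichromatism in passerine birds.
    Implements region-wise molt and dichromatism scoring with derived
    extent and presence variables, maximum-likelihood fitting of Brownian
    motion, Ornstein-Uhlenbeck, early-burst and Pagel's-lambda models with
    AICc weighting, Mk-model ancestral state reconstruction with
    equal-rates/all-rates-different likelihood-ratio tests, Pagel's test
    of correlated evolution for binary characters, phylogenetic
    generalized least squares with AICc-ranked model sets,
    simulation-based phylogenetic ANOVA with Holm correction, and
    d-separation phylogenetic path analysis with Fisher's C and CICc
    model ranking. A synthetic-data generator produces warbler-like trees
    and trait tables with the causal and phylogenetic structure the
    analysis assumes, so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    Matrix,
    pracma,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    yaml,
    jsonlite
LinkingTo: Rcpp
Config/testthat/edition: 3
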