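Package: ddinfer
Title: Parsimony Inference of Domain-Domain Interactions from Protein
    Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers domain-domain interactions (DDIs) that parsimoniously
    explain an observed protein-protein interaction (PPI) network.  Provides
    the pure parsimony-explanation cover model, its slack-budgeted integer
    linear programming form, and a weighted variant whose weights are derived
    from global network properties (Watts-Strogatz clustering, degree binning
    and disassortative mixing), all solved by LP relaxation with a built-in
    bounded-variable simplex.  Includes reliability-sampled LP-scores, witness
    counts and pw-scores, randomization tests for the parsimony assumption and
    for weight significance, Erdos-Renyi and degree-preserving null ensembles
    for the clustering coefficient, sensitivity/fold-change evaluation against
    a gold standard, and a synthetic-data generator with planted DDIs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
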