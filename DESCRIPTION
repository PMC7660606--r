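Package: grnensemble
Title: Ensemble Gene Regulatory Network Inference with
    Belief-Propagation Validation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from expression data
    by combining a partial-least-squares ensemble regulator scorer with a
    mutual-information and entropy-reduction network builder. Candidate
    regulators are called from gene-role frequencies over repeated seeded
    runs at a sweep of edge-density thresholds, and the information-theoretic
    network is refined by removing edges that point into identified
    regulators from non-regulators. Networks are validated computationally
    by two-level Gaussian-mixture quantisation, conversion to a factor
    graph, loopy belief propagation, and correlation of predicted marginals
    against observed state proportions. Also estimates effect sizes and the
    sample sizes needed to validate candidate regulators, and generates
    planted-regulator benchmark data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
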