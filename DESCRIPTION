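Package: consnet
Title: Dual-Network Inference of Hierarchies Among Modifiable Health Risks
Version: 0.1.0
Authors@R:
    person("consnet", "maintainers", email = "methods@example.org",
           role = c("aut", "cre"))
Description: Estimates relational hierarchies among modifiable health-risk
    variables from a single cross-sectional cohort using two complementary
    graphical models: a regularized partial correlation network (EBIC-selected
    graphical lasso with non-parametric edge bootstraps and case-dropping
    centrality-stability diagnostics) and a consensus Bayesian directed acyclic
    graph built by a double cross-consensus ensemble (four structure-learning
    algorithms crossed with four data transformations, bootstrap arc-strength
    averaging, ad-hoc strength/direction thresholding, and cross-grid
    consensus with learned and grand arc statistics). Includes a synthetic
    cohort generator with planted linear-Gaussian structural models for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
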