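Package: csodesign
Title: G- and D-Optimal Designs for Hierarchical Models via Competitive
    Swarm Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes G-optimal approximate designs for predicting
    individual parameters in hierarchical (random-coefficient) linear
    models, prediction D-optimal designs, and locally D-optimal designs
    for Poisson regression with random, possibly correlated coefficients.
    The minimax G-criterion is optimized with a competitive swarm
    optimizer (CSO), and candidate designs are certified by an
    equivalence theorem: the answering set of the prediction variance
    function is located, an optimal probability measure on it is fitted,
    and the resulting sensitivity function is checked to be nonpositive
    with roots at the support points.  Regression bases include
    polynomials, fractional polynomials under the Box-Tidwell convention,
    and multi-factor bases with interactions.  Closed-form results for
    random-slope and random-intercept models are included as analytic
    cross-checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
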