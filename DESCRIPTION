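Package: causalflip
Title: Exact Counterfactual Arithmetic for Confounding and Exchangeability of
    Association Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reasoning about confounding in the potential-outcomes
    (counterfactual) framework using exact rational arithmetic. Populations are
    described by response-type distributions (doomed, causal, preventive,
    immune) in the exposed and unexposed groups together with an exposure
    prevalence. The package computes causal risk differences and ratios for a
    chosen target population, factual and exposure-flipped (counterfactual)
    measures of association on the risk-difference, risk-ratio and odds-ratio
    scales, and decides -- exactly, with no floating-point tolerance -- the
    conditions of no confounding in distribution, no confounding in measure,
    and exchangeability of association measures under exposure flipping,
    including the shift and scale constants that characterise the latter two.
    A seeded simulator generates random and constrained populations for
    property-style verification of the logical relationships between these
    conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
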