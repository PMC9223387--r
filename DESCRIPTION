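Package: aquaflux
Title: Constraint-Based Modeling of Fish Metabolism, Growth and Feeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for constraint-based analysis of fish metabolic models:
    flux balance analysis (FBA) and parsimonious FBA on SBML/JSON models with
    an exact bounded-variable simplex core, amino-acid essentiality and
    metabolic-task screening, enumeration of minimal growth-supporting uptake
    and secretion sets, randomized oxygen-limited growth simulation with
    growth-curve fitting (piecewise-linear metabolic, logistic, and extended
    Monod forms), identification of growth-limiting amino acids in feed
    ingredients from mass-weighted reduced costs with iterative penalized
    supplementation and feed-efficiency accounting, and reaction-content
    comparison of metabolic models by hierarchical clustering with cophenetic
    correlation. Includes a generator for a compact salmon-like core model
    with known ground truth for testing all analyses offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
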