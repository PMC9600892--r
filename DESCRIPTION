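Package: steadycross
Title: Community Flux Balance Analysis and Cross-Feeding Inference for
    Two-Member Gut Microbial Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based metabolic modeling of small microbial
    communities growing on dietary fiber. Reads and curates genome-scale
    metabolic models (SBML Level 3 + FBC, or an equivalent JSON dialect),
    applies defined media with fiber-polymer carbon normalization, scores
    model phenotype predictions against experimental truth tables, and
    solves SteadyCom-style community problems: maximum balanced community
    growth by bisection over a feasibility LP, minimal fiber uptake at a
    fixed experimental growth rate, suboptimal fiber-budget relaxation,
    community flux-variability analysis, and artificial-centering
    hit-and-run Monte Carlo sampling of the community flux polytope.
    Sampled exchange fluxes are classified per member as produced,
    consumed or indeterminate by one-sample Wilcoxon tests, and pairwise
    coupling between member exchanges is quantified by correlation.
    Includes a synthetic fiber-degrader/butyrogen community generator
    with analytically known optima for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
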