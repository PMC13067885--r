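Package: fnirsBalance
Title: Posturography and fNIRS Brain-Network Topology for Static Balance Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Couples force-platform posturography with functional
    near-infrared spectroscopy (fNIRS) brain-network analysis for
    two-group, two-condition static balance designs. Computes
    center-of-pressure balance indices (sway area, RMS displacement,
    mean velocity), preprocesses raw two-wavelength optical recordings
    to oxyhemoglobin concentration changes via the modified
    Beer-Lambert law, builds region-of-interest functional-connectivity
    matrices, derives graph-theoretical network metrics (global, local
    and nodal efficiency, small-worldness against degree-preserving
    null ensembles) aggregated as area under the curve over a sparsity
    sweep, and runs the mixed-design ANOVA statistical layer with
    effect sizes, simple effects, multiplicity control and
    brain-behavior correlations. Includes a synthetic cohort generator
    with controllable group-by-condition effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
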