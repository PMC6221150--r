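Package: threshnma
Title: Bias-Adjustment Threshold Analysis for Network Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-threshold sensitivity analysis for network
    meta-analysis (NMA). Fits conjugate normal fixed-effect and
    fixed-tau2 random-effects NMA models in closed form, constructs the
    influence matrix mapping additive data perturbations to changes in
    posterior mean treatment effects, and derives bias-adjustment
    thresholds: the smallest changes to any study estimate, or to the
    combined evidence on a treatment contrast, that alter which
    treatment is recommended. Supports decision-invariant intervals,
    minimal clinically important differences, common-bias adjustments
    across sets of data points, two-dimensional invariant regions for
    simultaneous adjustments, and contrast-level analysis that
    reconstructs a hypothetical independent likelihood from a reported
    posterior summary by non-negative least squares with a
    Kullback-Leibler adequacy diagnostic.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools, pracma, igraph
Suggests: testthat (>= 3.0.0), yaml, jsonlite, MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
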