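Package: respgate
Title: Intra-Beam Respiratory Motion, Baseline Drift and Gated-Dose Analysis for Lung SBRT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing intra-beam respiratory motion in
    respiratory-gated lung stereotactic body radiotherapy (SBRT). Generates
    synthetic fiducial-marker breathing traces with controllable per-cycle
    amplitude/period variability and baseline drift; detects per-cycle
    expiration points and quantifies baseline drift as the per-cycle slope
    between consecutive expiration positions; simulates phase-gating and
    amplitude-gating windows and the residual target motion inside them; and
    propagates the gated target-position probability density into a convolved
    dose distribution, dose-volume histogram and homogeneity index
    (D2-D98)/D50 using the van Herk dose-convolution method over an analytic
    plateau-penumbra reference plan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
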