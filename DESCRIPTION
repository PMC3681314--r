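Package: rootflux
Title: Morphogen Gradient Mechanisms in the Plant Root
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic calculators, cell-file models and a cell-resolution 2D
    tissue simulator for contrasting three morphogen-gradient-generating
    mechanisms in the plant root tip: source-decay (localised production,
    diffusion and linear turnover), unidirectional polar transport along a
    cell file, and the PIN-mediated reflux loop.  Includes a minimal-root
    layout generator with tissue-specific PIN permeability maps, steady-state
    and transient finite-volume simulation of auxin transport (intracellular
    and apoplastic diffusion, carrier-mediated membrane fluxes, decay and
    influx), longitudinal profile extraction with exponential-gradient
    fitting and elbow detection, and a scenario runner for gradient
    establishment, influx-cut/ablation and robustness experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
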