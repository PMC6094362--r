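Package: microswim
Title: Hydrodynamic Performance Prediction and Optimization of Flagellated
    Microswimmers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting and optimizing the swimming performance
    of a model robotic bacterium (spherical head plus rotating helical
    flagellum) in Stokes flow.  Implements resistive force theory drag
    models, Purcell's additive approximation, a fully coupled
    regularized-Stokeslet boundary-integral solver for rigid-body
    resistance matrices and partwise resistance blocks, a geometric
    correcting factor that repairs the simplified speed predictions, six
    swimming performance measures, and flagellar-length sweeps and
    optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
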