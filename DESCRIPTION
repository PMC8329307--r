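Package: gslpode
Title: Generalized Shifted Legendre Spectral Optimization for Caputo
    Fractional Differential Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Solves systems of nonlinear Caputo fractional-order ordinary
    differential equations by expanding each state in a generalized shifted
    Legendre polynomial (Muntz-type) basis with free exponent shifts,
    applying the diagonal Caputo operational matrix, and minimizing the
    integrated squared residual subject to initial-condition constraints via
    bound-constrained Levenberg-Marquardt with multistart. Bundles a fully
    parameterized fractional breast cancer competition model (coupled
    dynamics of cancer stem, tumor, healthy and immune cells and excess
    estrogen) as the showcase system, together with an independent
    fractional Adams-Bashforth-Moulton predictor-corrector integrator and
    analytic/quadrature Caputo derivative oracles for cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    graphics,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
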