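Package: sindypi
Title: Parallel Implicit Sparse Identification of Nonlinear Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers implicit dynamical systems and rational-function
    nonlinearities from time-series and spatio-temporal data by parallel
    sparse regression over candidate left-hand-side terms (SINDy-PI).
    Includes sequentially thresholded least squares and constrained
    joint solvers, the null-space/ADM implicit-SINDy baseline, an
    explicit PDE regression baseline, total-variation regularized
    differentiation, model selection on held-out data, and seeded
    simulators for enzyme-kinetics, metabolic-network, mechanical and
    reaction-diffusion benchmark systems.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
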