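Package: cveukinetics
Title: Cell Kinetics of the Intestinal Crypt-Villus Epithelial Unit from
    Pulse-Chase Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies epithelial cell proliferation and migration along
    the one-dimensional crypt-villus epithelial unit (CVEU) from thymine
    analog (BrdU/IdU) pulse-chase scoring data. Implements a two-compartment
    threshold-gated model of labeled-cell propagation with explicit
    piecewise solutions, nonlinear least-squares fitting on the log(L+1)
    scale, estimation of the crypt-villus boundary from two-hour labeling
    profiles, derivation of mitotic-pressure velocities and crypt-to-tip
    transit times, Monte Carlo posterior comparison of crypt cell
    production rates across experimental groups, and an agent-based CVEU
    simulator for generating pulse-labeling datasets under control,
    reduced-proliferation and transient proliferation-arrest regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
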