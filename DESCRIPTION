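Package: stochbif
Title: Stochastic Bifurcation Analysis of One-Variable Gene Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies how intrinsic biochemical noise shifts the
    saddle-node bifurcation points of one-dimensional gene regulatory
    systems, with the auto-activating genetic switch as the reference
    model. Provides the analytic stationary density of the Ito chemical
    Langevin equation and its extrema, numerical continuation of the
    stochastic bifurcation conditions, a perturbative expansion of the
    bifurcation points in powers of the noise intensity (including the
    long-correlation-time colored-noise limit), the exact birth-death
    master-equation stationary distribution via detailed balance,
    Euler-Maruyama and Stratonovich-consistent colored-noise integrators,
    Gillespie simulation of the simple and promoter-binding switch models,
    and a landscape pipeline (empirical densities, Gaussian peak detection,
    dwell-time statistics, stochastic bifurcation diagrams).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
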