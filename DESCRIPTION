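Package: crowddiff
Title: Effective Solute Diffusivity in Crowded Macromolecular Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the effective diffusivity of a small solute in a
    macromolecular (polymer) solution from measurable physical parameters
    alone. The polymer molecules are modelled as impenetrable spheres on a
    simple cubic lattice; a periodic-homogenization unit-cell problem is
    solved by a finite-volume method to obtain the effective diffusivity as
    a function of a single dimensionless obstruction parameter. Two Monte
    Carlo obstructed-random-walk simulators (an Euler-discretized reflected
    Wiener process and an exponential-step velocity-jump model) cross-check
    the continuum result via mean-squared-displacement analysis. Closed-form
    comparators (Maxwell-type effective-medium formulas, an exponential law)
    and fluorescence correlation spectroscopy (FCS) autocorrelation fitting
    support comparison with experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
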