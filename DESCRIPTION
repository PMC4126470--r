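Package: memelast
Title: Elastic Constants of Coarse-Grained Lipid Bilayers from Monte Carlo Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Metropolis Monte Carlo simulation of a coarse-grained single-tail
    lipid bilayer (bead-spring amphiphiles with FENE bonds, bond-angle
    stiffness, shifted soft-core pair interactions and a phantom solvent) in
    the NPT ensemble with anisotropic box moves. Implements a box-rescaling
    protocol that measures the Poisson's ratio of a periodic membrane from
    the transverse relaxation after a uniaxial strain, extracts the bending
    rigidity from a Helfrich fit to the height-fluctuation power spectrum on
    a gridded midplane, and combines both into the Young's modulus through
    the thin-plate relation. Includes synthetic-system generators (Helfrich
    height-field ensembles, periodic triangular spring lattices, phantom
    gases) that serve as analytic oracles for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
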