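Package: sonoguide
Title: Brownian-Dynamics Simulation of Collectively Guided Acoustically
    Propelled Magnetic Microparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the collective guiding of acoustically propelled,
    magnetically aligned nano- and microparticles towards a target.  A
    focused-ultrasound beam (spherical-cap transducer, attenuated
    Rayleigh-Sommerfeld integral, or its spheroidal-Gaussian surrogate)
    supplies intensity-scaled propulsion, a slowly co-rotating homogeneous
    magnetic field aligns the particle orientations towards the target, and
    overdamped Langevin dynamics with Weeks-Chandler-Andersen interactions
    evolves the ensemble, either in a homogeneous environment or confined to
    a random channel network generated by persistent random walks.  Includes
    an inward-spiral focus-trajectory planner, observables (radial packing
    density, target fraction, distance quantiles, ensemble statistics), and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
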