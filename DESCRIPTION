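Package: ipswater
Title: Isotropic Periodic Sum Electrostatics for SPC/E Water Under
    Atom- and Group-Based Cut-Off Schemes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A minimal molecular dynamics engine for rigid SPC/E water
    built to compare truncation treatments of the electrostatic
    interaction. Implements the isotropic periodic sum (IPS) family of
    pair potentials (IPSn, IPSp, LIPS-5th, LIPS-SW) by solving their
    cut-off boundary conditions, writes them as tabulated interaction
    functions, and evaluates them under atom-based or group-based
    cut-off schemes with an optional pseudo cut-off radius. A direct
    Ewald summation serves as the accuracy reference at small system
    sizes. Includes velocity-Verlet integration with SHAKE/RATTLE
    constraints and a single-chain Nose-Hoover thermostat, builders for
    bulk and water-vapour slab configurations, and the observable suite
    used to diagnose cut-off artefacts: self-diffusion by the Einstein
    relation, radial distribution functions, the distance-dependent
    Kirkwood factor, the dipole-ordering function, and density and
    electrostatic potential profiles along a surface normal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
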