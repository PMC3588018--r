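Package: mlpb
Title: Modified Langevin-Poisson-Boltzmann Electrostatics of Zwitterionic Lipid Headgroup Layers
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Mean-field electrostatics of a planar zwitterionic (dipolar) lipid
    headgroup layer in contact with a monovalent salt solution. Solves the
    modified Langevin-Poisson-Boltzmann (MLPB) boundary-value problem, in which
    the water permittivity depends on the local electric field through Langevin
    orientational ordering of water dipoles with an Onsager cavity-field
    correction, and the positive charge of each headgroup dipole is distributed
    over the headgroup region by a Boltzmann (or finite-volume lattice)
    probability density. Computes spatial profiles of electric potential,
    relative permittivity, ion densities, and headgroup charge, the average
    headgroup dipole orientation angle, and temperature sweeps across the
    DPPC gel/liquid-crystalline phase transition. Includes a Gouy-Chapman
    closed-form reference for validation and a small command-line driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    pracma,
    yaml,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
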