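Package: alveonet
Title: Spring-Network Simulation of Alveolar Wall Destruction and Lung
    Tissue Stiffness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a pre-strained cuboidal block of lung parenchyma as a
    space-filling network of polyhedral alveoli (cubes or tetrakaidecahedra)
    whose walls are tension-only spring assemblies. Alveolar wall destruction,
    as in emphysema, is mimicked by removing faces at random, by highest
    carried force, or by a mixture of the two; after each step the network is
    re-equilibrated by energy minimization and the airspace-volume
    distribution and bulk modulus are measured. A Karhunen-Loeve (principal
    component) reduction of the first four moments of airspace volumes,
    combined with a least-squares plane fit, provides an estimator of the
    decline in bulk modulus from structure alone, and tools are included to
    evaluate that estimator across lattice geometries, pre-strains,
    constitutive laws and destruction patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
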