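Package: memclust
Title: Aggregation Kinetics and Hydrodynamics of Membrane Inclusions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of lateral self-assembly of cylindrical inclusions
    (e.g. carbon-nanotube porins or transmembrane proteins) in lipid
    membranes from 2D center-of-mass trajectories. Provides dual-cutoff
    cluster identification under periodic boundary conditions, cluster
    growth kinetics and power-law fitting, 2D radial distribution
    functions, tilt-order statistics, per-cluster-size diffusion
    coefficients from mean-squared displacements with finite-size
    correction, and membrane-viscosity estimation by fitting the
    Saffman-Delbruck and Hughes-Pailthorpe-White (Petrov-Schwille)
    hydrodynamic models. Includes a Brownian-dynamics generator of
    synthetic aggregation trajectories with membrane-hydrodynamic
    mobilities for validation and method development.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
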