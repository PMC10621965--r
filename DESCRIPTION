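Package: collateralflow
Title: Blood Flow Simulation and Diameter Tuning in Cerebral Microvascular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates semi-realistic cortical microvascular networks (pial
    surface arteries, penetrating arterial and venous trees, a stacked
    hexagonal capillary lattice), solves steady Poiseuille blood flow with the
    empirical diameter- and haematocrit-dependent relative viscosity of Pries
    and co-workers, tunes vessel diameters to sparse red-blood-cell velocity
    constraints by adjoint-based projected gradient descent, and quantifies
    blood-flow redistribution under middle-cerebral-artery occlusion,
    leptomeningeal-collateral dilation and arterial dilation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
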