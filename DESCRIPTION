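Package: padmech
Title: Voxel Finite-Element Modelling and Topology Optimisation of
    Tree-Frog Digital Pad Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reimplements, as a tested pipeline, the structural-mechanics
    analyses of the ventral collagen layer of tree-frog digital pads: a
    parametric voxelised pad model pierced by mucus-duct holes, a
    small-strain linear-elasticity solver on trilinear hexahedra with
    density-modulated (SIMP) stiffness, compliance-minimising topology
    optimisation under a stepped volume-reduction schedule, principal
    stress trajectory tracing and von Mises stress contrasts, analytic
    tensile-strength load budgets of the force-transmitting structures,
    and peeling mechanics (Kendall thin-film peel force and a
    septum-loading contact-stress comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
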