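Package: atflap
Title: Geometric Design and Finite-Element Evaluation of A-T Advancement Flaps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Preoperative evaluation toolkit for A-T (O-T) local advancement
    flaps. Provides the closed-form geometric design model linking defect
    radius and apex angle to flap length-width ratio, maximum suture distance
    and suture area, with constraint-based selection of the optimal apex
    angle; an incompressible Ogden hyperelastic skin material model with
    uniaxial closed forms and nonlinear least-squares fitting to
    stress-stretch data; block-structured quadrilateral meshing of the
    operative skin region with incision cuts and suture node pairing; and a
    two-dimensional total-Lagrangian plane-stress finite-element solver that
    simulates the suture and release stages of the operation, reporting von
    Mises stress and displacement fields, mesh quality and mesh-sensitivity
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
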