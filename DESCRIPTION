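Package: facesim
Title: Simulation of Surgically Plausible Facial Disfigurement on 3D Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to learn and simulate facial disfigurement arising from
    reconstructive surgery on colored 3D surface meshes. A reference
    ("mannequin") head is brought into dense vertex-level correspondence with
    target faces by Procrustes alignment, thin-plate-spline landmark warping
    and piecewise-linear radial interpolation in cylindrical coordinates.
    Longitudinal structural and textural change within a patient is captured
    by snapshot principal component analysis (the eigen-disfigurement), and a
    learned disfigurement is stitched seamlessly onto a novel face by solving
    the discrete Poisson equation with Dirichlet boundary conditions on the
    mesh graph, with controllable type, location and severity. Includes
    seeded synthetic-face generators, per-channel contrast-stretch color
    normalization, evaluation utilities (validation-fiducial error, fiducial
    perturbation sensitivity, observer-rating summaries) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    tools,
    tibble,
    utils,
    stats,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
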