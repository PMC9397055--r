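Package: scaffoldflow
Title: Perfusion Modelling of 3D-Printed Bone Tissue-Engineering Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry-based perfusion modelling for extrusion-printed bone
    tissue-engineering scaffolds. Builds parametric 0/90 lay-down and
    pore-size-graded ring scaffold solids, computes their porosity and
    specific surface area, voxelizes them into labelled flow domains, and
    solves steady incompressible Newtonian flow through the pore network
    with a D3Q19 two-relaxation-time lattice-Boltzmann solver. From the
    flow field it derives pressure drop, Darcy intrinsic permeability,
    interstitial Reynolds number, wall shear stress (WSS) fields, and the
    fraction of scaffold surface below a WSS viability threshold (default
    30 mPa), over sweeps of inlet blood-flow velocity. Includes analytic
    channel fixtures (plane Poiseuille, Hagen-Poiseuille) for solver
    validation, STL/VTK/CSV export, YAML run configuration and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
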