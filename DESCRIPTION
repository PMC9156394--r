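Package: etsflow
Title: Steady Laminar Hemodynamics of End-to-Side Anastomoses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale computational hemodynamics of an end-to-side (ETS)
    microvascular anastomosis between a graft artery and a donor artery.
    Builds a parametric 2-D mid-plane model of the junction at a chosen
    anastomotic angle, meshes it with a block-structured finite-volume grid,
    solves steady incompressible Newtonian Navier-Stokes flow with a
    SIMPLE-type pressure-velocity coupling, and quantifies the three result
    surfaces relevant to anastomotic patency: recirculation zones, per
    cross-section flow stagnation in the graft, and wall shear stress along
    the vessel walls. Includes an angle-sweep driver, an ordinary
    least-squares model of maximum stagnation versus anastomotic angle, a
    verification suite (Poiseuille benchmarks, manufactured solutions,
    constructed post-processing fixtures), and plain-text exporters (VTK
    legacy grids, CSV profiles, JSON metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
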