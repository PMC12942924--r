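Package: phototherm
Title: Delta-P1 Light Transport and Pennes Bioheat Finite Elements for
    Photothermal Therapy Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled light-transport and bioheat simulation of laser-driven
    photothermal therapy in axisymmetric heterogeneous tissue. Solves the
    delta-P1 (delta-Eddington) approximation, the standard diffusion
    approximation and the Beer-Lambert law for the optical fluence rate on
    r-weighted P1 triangular finite-element meshes, and feeds the absorbed
    power into a transient Pennes bioheat solver with backward-Euler time
    stepping, convection and Dirichlet boundaries. Includes a compiled voxel
    Monte Carlo photon-transport reference (Henyey-Greenstein scattering,
    implicit capture, Russian roulette, Fresnel surface reflection), an
    analytical semi-infinite delta-P1 solution for validation, region-averaged
    temperature and RMS/relative error metrics, mesh-convergence and
    optical-property sweep drivers, YAML case configuration, and VTK/CSV/JSON
    exporters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
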