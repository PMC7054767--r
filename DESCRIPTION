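Package: vffr
Title: Virtual Fractional Flow Reserve from 2D Finite-Element Coronary
    Haemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulsatile blood flow in multi-branch stenotic
    coronary-tree geometries with a generalized-Newtonian (Carreau)
    rheology and 2-element Windkessel outlet boundary conditions, and
    estimates the fractional flow reserve (FFR) the way the clinical
    pressure-wire device does: cycle-wise temporal means of an aortic-box
    pressure and of the pressure on a sensor-disk contour placed distal to
    each lesion. Includes a parametric synthetic coronary-tree generator
    with cosine-profile stenoses and meshed sensor-disk obstacles, a
    Taylor-Hood (P2/P1) semi-implicit incompressible Navier-Stokes solver,
    coupled-multidomain Windkessel outflow operators, and experiment
    drivers for mesh-refinement convergence, outlet-boundary-condition and
    flow-model comparisons, and sensor-placement sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    yaml,
    jsonlite,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
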