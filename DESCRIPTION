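Package: larvadrift
Title: Synthetic Submesoscale Flows, Lagrangian Larval Tracking and Site
    Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying how wind-driven coastal
    currents and submesoscale features (filaments and eddies with order-one
    Rossby number) shape the dispersal of passive larvae. Provides analytic,
    divergence-controlled synthetic velocity fields emulating prevailing
    northeasterly-wind and cold-front wind regimes on a regular lon/lat grid;
    mask-aware finite-difference diagnostics (relative vorticity, Rossby
    number, normalized strain rate); three-dimensional passive particle
    tracking with fourth-order Runge-Kutta advection, bilinear mask-aware
    interpolation and a vertical random walk; and polygon-based connectivity
    matrices, integrated density plumes and final-population statistics.
    Velocity fields, diagnostics and trajectories are read and written as
    CF-style NetCDF so externally produced ocean-model output can be
    substituted for the synthetic fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    ncdf4,
    stats,
    utils,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
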