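Package: crimdyn
Title: Dynamics of Criminal Organizations and a Corruptible Judiciary
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a four-compartment nonlinear ODE model of the
    interplay between a criminal gang, non-corrupt judges, corrupt judges,
    and prisoners. Gang growth is logistic with a carrying capacity, judges
    incarcerate gang members (predator-prey coupling), gang members co-opt
    judges, and released prisoners may relapse. The package provides the
    closed-form equilibria E0-E6 for the four structural cases defined by
    the recidivism and co-optation rates, the basic reproduction number R0
    and its elasticities, the backward- and transcritical-bifurcation
    thresholds r, r1, r2, analytic and numeric local stability
    classification (eigenvalues, Routh-Hurwitz), a fixed-step fourth-order
    Runge-Kutta integrator with attractor detection and basin probing,
    bifurcation-diagram construction over the gang growth parameter, and
    shipped scenario fixtures with a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
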