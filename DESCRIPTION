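Package: biocontinuum
Title: Entropic Replicator Dynamics and Information Geometry for Biosystems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulates replicator and Lotka-Volterra dynamics over a
    probability simplex of biological state types and tracks the
    information-theoretic observables that shape those trajectories:
    Shannon entropy and its exact production rate, Kullback-Leibler
    divergence from a fixed target state together with its rate (used as a
    Lyapunov function), and an information action functional built from
    kinetic (dI/dt) and potential (I) information.  Also provides the
    information geometry of the state space: Fisher information metrics on
    the categorical simplex (Shahshahani form) and on the Gaussian
    location-scale manifold, closed-form Fisher-Rao geodesic distance, and
    natural-gradient descent flows.  Scenarios are defined in JSON,
    trajectories exported as CSV, and a seeded random-scenario generator
    supplies reproducible fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
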