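Package: coexdyn
Title: Compartmental Dynamics of Racism and Corruption Coexistence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic seven-compartment transmission model for the joint
    spread of two social contagions (racism and corruption) in a community,
    treated as mind infections. Provides the coupled ordinary differential
    equation system and its single-contagion submodels, next-generation-matrix
    reproduction numbers, closed-form and numerically root-found equilibria,
    local stability via Jacobian eigenvalues and Routh-Hurwitz criteria,
    sampled Lyapunov-type global-stability checks, center-manifold bifurcation
    coefficients at the transmission threshold, normalized forward sensitivity
    indices with threshold scans, a seeded scenario generator, stiff-capable
    time integration, and a discrepancy audit of published summary figures
    against the model's own closed forms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
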