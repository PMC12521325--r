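Package: chiralchase
Title: Chiral Chase-and-Run Dynamics in Nonlocal Advection-Diffusion Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pattern formation in two-species nonlocal
    (integro-differential) advection-diffusion models with chiral movement,
    in which chasers pursue runners and either species may veer off at an
    angle from the line of separation. Provides the interaction-kernel
    Hankel transforms and dispersion relations for linear stability
    analysis, regime classification and phase diagrams, linear predictors
    of species mixing versus separation, an FFT-based periodic-domain
    simulator for both direct-sensing and gradient-sensing model variants,
    and diagnostics for the emergent nonlinear structures: oscillation
    detection, aggregate counting, and periodic-domain trajectory tracking
    with signed curvature for population-level chase-and-run pulses and
    travelling holes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
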