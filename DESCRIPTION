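Package: tnfkin
Title: Kinetic and Equilibrium Analysis of TNF-alpha Trimer-Monomer
    Dynamics and Scavenger Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for biosensor studies of tumor necrosis
    factor-alpha (TNF-alpha) oligomeric state and its therapeutic
    scavengers. Provides closed-form mono- and bi-exponential decay
    models, pseudo-first-order association kinetics, the
    depletion-corrected equilibrium binding isotherm, and
    switching-speed/hydrodynamic-diameter conversions; global nonlinear
    least-squares fitting with shared rate constants across
    concentration series; decay-model selection; solution-equilibrium
    affinity titration with bootstrap confidence intervals; and a
    trimer-stabilization panel comparison across antibody formats.
    Seeded synthetic-trace generators emulate electro-switchable
    biosensor experiments so every analysis stage can be exercised and
    validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
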