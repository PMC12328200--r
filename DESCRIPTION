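Package: redoxmotor
Title: Kinetics and Stochastic Simulation of a Redox-Driven Biaryl Rotary
    Molecular Motor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the dissipative cyclic redox reaction network that drives
    autonomous directional rotation about a biaryl C-C single bond under
    enzyme control. Provides Eyring barrier/rate conversions and rate-law
    analytics for the network's rate hierarchy, a deterministic ODE model of
    the coupled enantioselective oxidation / non-selective borane reduction /
    fast enantiomerization cycle (deracemization and motor topologies, with
    fuel depletion and pulse schedules), a stochastic per-molecule motor
    simulator yielding net-rotation statistics and deuterium-incorporation
    bookkeeping, isotopomer-based estimators of oxidation enantioselectivity
    and kinetic isotope effect with bootstrap uncertainty, and seeded
    synthetic-data generators for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
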