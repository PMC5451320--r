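Package: wcsim
Title: Multi-Algorithm Whole-Cell Simulation with a Central Request Controller
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Composes pathway submodels written in heterogeneous mathematical
    formalisms (Gillespie stochastic simulation, deterministic mass-action
    ODEs, dynamic flux balance analysis, and Boolean regulatory rules) into a
    single whole-cell model sharing a global pool of integer molecule counts.
    Each time step, every submodel is integrated from the same immutable state
    snapshot and proposes species changes as requests; a central controller
    arbitrates conflicting consumption by proportional largest-remainder
    scaling, adapts the step size, and commits a non-negative global state.
    Includes a reader/writer for an SBML Level 3 core subset (with the flux
    balance constraints idiom), a JSON/YAML composition manifest, trajectory
    export, and programmatic model generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
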