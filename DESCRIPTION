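Package: itmsim
Title: PBPK Simulation of Intra-Target Microdosing Feasibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiologically based pharmacokinetic (PBPK) modelling of
    intra-target microdosing (ITM) trials. Implements a whole-body PBPK model
    with explicit drug-receptor binding kinetics in a target tissue, a Monte
    Carlo generator of virtual small-molecule compounds from log-normal
    parameter distributions, an automated therapeutic-dose finder based on a
    receptor-occupancy criterion, a simulator of intra-target microdose
    administration, and study-level analyses (success probabilities with
    Wilson intervals, decile subgroup tables, fixed-parameter sweeps) that
    quantify when a microdose delivered directly to the target tissue can
    reach therapeutic levels of target engagement.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    MASS,
    stats,
    utils,
    yaml,
    jsonlite,
    parallel
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
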