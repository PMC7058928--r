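Package: norcircuit
Title: Design and Simulation of Transcriptional NOR-Gate Circuits with
    Tandem-Promoter Interference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A design-automation toolkit for transcriptional logic circuits
    built from repressor-based NOT/NOR gates. Implements Hill response
    functions with a roadblock-interference correction for tandem input
    promoters, steady-state circuit prediction over acyclic netlists,
    truth-table-to-NOR logic synthesis with don't-care support,
    constraint-aware assignment of library gates to circuit nodes
    (exhaustive or simulated annealing), two-timescale ODE dynamics under
    piecewise-constant inducer schedules, total RNA-polymerase-flux power
    accounting, and parameter fitting from dose-response, tandem-quadrant
    and time-course data with synthetic-data generators for recovery
    studies. Ships a characterized 18-gate repressor library and the
    BCD-to-7-segment decoder truth tables as worked fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    deSolve,
    minpack.lm,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
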