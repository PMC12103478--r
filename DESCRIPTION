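Package: pressorloop
Title: Closed-Loop Lower-Limit Phenylephrine Delivery: Controller, Virtual
    Patients, and Trial Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A testable implementation of a rule-based closed-loop system for
    automated phenylephrine administration driven by intermittent noninvasive
    blood-pressure (NIBP) readings. Provides the lower-limit control state
    machine that issues bolus doses and titrates a continuous infusion when
    mean blood pressure falls below a hypotension threshold; a seeded
    virtual-patient simulator (one-compartment pharmacokinetics with a
    saturating pressor effect) to exercise the loop without clinical data;
    time-in-range endpoint metrics, consecutive-hypotension run tabulations,
    and Varvel performance-error indices; and the non-inferiority t-test
    machinery used to compare treatment arms from per-patient endpoints or
    published group summaries. A small command-line pipeline ties simulation,
    replay, evaluation, and trial analysis together reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
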