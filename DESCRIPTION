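Package: livewell
Title: Rule-Based Expert System Engine for Adaptive Bipolar Disorder Self-Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the adaptive engine of a smartphone self-management
    intervention for bipolar disorder: a four-state clinical-status state
    machine driven by daily wellness ratings, a nine-state DSM-IV/clinical
    monitoring form (CMF) state machine driven by symptom-severity streams,
    hierarchical decision tables selecting one of 26 daily-review content
    categories, clinical reach-out and adherence alerting rules, check-in
    notification scheduling, and seeded simulators of user check-in
    trajectories and content corpora so that every rule path can be
    exercised without patient data. All rule thresholds live in an
    overridable configuration object.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
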