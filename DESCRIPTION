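Package: multirate
Title: Multi-Rate State-Space Modeling of Anterograde Interference in
    Motor Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-by-trial simulation of the two-process (fast/slow)
    multi-rate state-space model of motor adaptation, construction of
    AB force-field training schedules with interleaved error-clamp
    probes, regression-based adaptation indices from lateral force
    traces, a zero-crossing-aligned anterograde-interference metric,
    constrained model fitting with subject-level bootstrap confidence
    intervals, and a synthetic-cohort generator so the full analysis
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
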