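Package: pipecap
Title: Capacity-Limited Pipelined Processing Models and Steady-State Rate
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates limited-capacity, pipelined, two-module information
    processing systems under additive-workload, multiplicative-workload and
    flexible-capacity models; converts behavioral event streams from
    object-hit style rapid motor tasks into smoothed instantaneous rates via
    a Kolmogorov-Zurbenko filter; extracts steady-state hit rates by
    detecting the overwhelmed phase of a trial with windowed median and
    median-absolute-deviation statistics; and performs Bayesian
    difference-of-rates and robust t-regression analyses with region of
    practical equivalence (ROPE) decisions based on 95% highest-density
    intervals. Includes a synthetic cohort and trial generator so every
    stage of the pipeline can be exercised and validated without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    coda,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    rjags,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
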