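Package: opiumdyn
Title: Dynamic Compartmental Modelling of Opium-Dependence Treatment Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time (annual) stock-and-flow simulation of opium-dependence
    treatment in a national population with four compartments: methadone
    maintenance treatment (MMT), buprenorphine maintenance treatment (BMT),
    detoxification with relapse prevention, and untreated or
    non-evidence-based care. Supports treatment-coverage change scenarios
    over a multi-decade horizon under constant prevalence and demographic
    growth, per-year and per-decade scenario contrasts (including a
    decade-level sum-of-relative-change statistic), Monte-Carlo parameter
    uncertainty propagation with percentile intervals, and an agent-based
    microsimulation oracle for validating the deterministic dynamics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
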