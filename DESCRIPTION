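Package: repool
Title: Shared-Control Designs for Two-Stage Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and calibrating two-stage (discovery plus
    replication) case-control association studies in which control samples
    are re-used between stages. Computes the null correlation structure
    induced among the discovery, replication and meta-analytic Z-statistics
    by sample sharing, solves for the adjusted replication p-value
    thresholds that conserve the joint type-1 error rate of the standard
    independent-cohorts design, and compares power and type-1 error
    profiles of the standard, shared-control and fully-pooled-control
    designs, including under cohort aberrance and control
    misascertainment. A seeded Monte-Carlo simulator of per-cohort allele
    counts reproduces every analytic quantity empirically.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
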