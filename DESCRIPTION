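Package: hrgap
Title: Workload-Based Estimation of Primary-Care Workforce Gaps
Version: 0.1.0
Authors@R: person("hrgap", "maintainers", email = "hrgap@example.org",
    role = c("aut", "cre"))
Description: Estimates the gap between the available and the ideal supply of
    primary-care human resources (physicians, nurses, health promoters) needed
    to deliver a guaranteed package of prevention and health-promotion
    activities. Available supply is accounted from facility headcounts and
    contracted working time; ideal supply is derived from normative per-person
    annual service minutes (time used and time required) multiplied by the
    attended population. Supplies are converted to full-time equivalents,
    compared across facilities with Wilcoxon signed-rank and Friedman tests,
    and screened with a gamma-distribution skewness sensitivity analysis. A
    seeded synthetic-study generator reproduces the statistical structure of a
    facility-level elicitation dataset so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
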