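Package: oacost
Title: Societal Costing and Cost-Effectiveness of Digital and Face-to-Face
    Osteoarthritis Care Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Micro-costing engine for comparing first-line osteoarthritis care
    delivered through a digital platform with face-to-face group-based care,
    from a societal perspective. Values provider and patient time with the
    human capital method (employer social fees, facility surcharges,
    leisure-time fractions), allocates group sessions, amortizes one-off
    training, and costs patient transport together with the carbon emissions
    it causes. Computes incremental cost-effectiveness ratios on pain-score
    outcomes with dominance classification, deterministic and probabilistic
    sensitivity analyses, and program-level substitution (budget impact)
    scenarios. Ships a synthetic-cohort generator so the whole pipeline is
    testable bottom-up without patient data, plus YAML care-model
    configurations, table-shaped report writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
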