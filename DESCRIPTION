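Package: franchiseCEA
Title: Cost-Effectiveness of Social-Franchise Promotion of ORS plus Zinc
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-tree cost-effectiveness analysis of promoting a
    co-packaged oral rehydration salts and zinc (ORS-Z) product for
    childhood diarrhea through a social franchise of private providers,
    from the societal and medical payer perspectives. Implements
    value-chain unit costing with payer attribution, launch-cost
    amortization and shared-overhead allocation; a two-arm four-terminal
    decision tree with probability calibration from printed cost tables,
    fold-back expected costs and scaling to a standard population of one
    million; coverage-increment effectiveness estimation (pre-post and
    difference-in-differences) with conversion of deaths averted to
    discounted disability-adjusted life years; second-order Monte Carlo
    probabilistic sensitivity analysis with triangular and truncated-normal
    parameter sampling, ICER summaries, tornado-diagram regression,
    cost-effectiveness-plane output and GDP-per-capita threshold
    classification; and a synthetic two-arm two-period household-survey
    generator with individual-level probability and cost estimators.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
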