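Package: tendocea
Title: Cost-Utility Analysis of Operative Versus Non-Operative Management
    of Acute Achilles Tendon Rupture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort cost-utility model comparing open operative
    repair with functional non-operative management of acute Achilles
    tendon rupture over a two-year horizon of three-month cycles, from the
    societal perspective (2014 US dollars). Provides the cohort engine
    with time-dependent utilities and recurrent re-rupture surgery,
    incremental cost-effectiveness ratios with dominance classification
    and net monetary benefit, calibration of unpublished complication
    event costs to published cohort totals, deterministic one-way
    sensitivity analysis with automatic threshold bisection and tornado
    ranking, and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves. Includes generators for the
    published base case, random valid scenarios for property testing, and
    degenerate scenarios with closed-form answers.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
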