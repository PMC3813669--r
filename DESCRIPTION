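Package: ginitrend
Title: Population-Weighted Gini Trends and Change-Point Regression for
    Health-Workforce Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying geographic inequality in the distribution
    of physicians (or any provider workforce) across spatial units within
    regions, and for testing whether the inequality trend changed after a
    policy intervention. Builds population-weighted Lorenz curves and Gini
    coefficients per region-year (with the n/(n-1) small-sample adjustment),
    harmonizes administrative-boundary changes through a crosswalk, fits
    fixed-knot linear change-point (segmented) regressions to the Gini panel
    with conventional or cluster-robust standard errors, stratifies fits by
    urban/rural classification schemes, and generates synthetic
    municipality-level panels with a controllable inequality trajectory and
    slope break for end-to-end validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lmtest,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
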