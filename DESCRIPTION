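Package: bnhybrid
Title: Hybrid Constraint-and-Score Structure Learning for Discrete Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns discrete Bayesian networks with hybrid algorithms that
    compose constraint-based neighbourhood discovery (MMPC and the IAMB family:
    plain, interleaved, fast) with score-based orientation by tabu search or
    hill climbing over BIC. Includes G-squared conditional independence
    testing, forward sampling from bundled benchmark networks, structural
    error metrics (reversed, missing, extra edges and their weighted total),
    maximum-likelihood parameter fitting, exact posterior inference by
    variable elimination for sequential risk reasoning, and an
    epidemiological comparison pipeline (chi-square screening, trend tests,
    stepwise logistic regression with odds ratios) built around a synthetic
    hyperlipidemia survey. Networks are read and written in BIF and a JSON
    dialect; results are tidy tibbles with broom-style tidiers and ggplot2
    autoplot methods.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
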