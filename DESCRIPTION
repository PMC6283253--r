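Package: agestage
Title: Age x Stage-Classified Matrix Population Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and analysis of age x stage-classified matrix
    population models using the vec-permutation block formulation.
    Builds block-Leslie projection matrices from per-age-class stage
    transition and fertility matrices; computes life-table functions
    (survivorship, mortality, intra-cohort selection, fertility
    schedules), absorbing-Markov-chain statistics of longevity with a
    within/between-stage variance decomposition, the joint distribution
    of age and stage at death and life disparity, population growth
    rate, stable structure and reproductive value, the
    next-generation-matrix net reproductive rate and lifetime
    reproduction, cohort generation times, and exact matrix-calculus
    sensitivity analysis of any output with respect to any parameter
    vector. Includes a synthetic poecilogonous example species, a
    schedule-table loader, hand-checkable toy models, and an
    individual-based Monte Carlo simulator used as an independent check
    on the analytic theory.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
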