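Package: radcea
Title: Lifetime Markov Cohort Cost-Effectiveness Analysis for Adjuvant
    Breast Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Config-driven Markov cohort state-transition modelling for
    comparing adjuvant radiotherapy strategies (intraoperative versus
    external-beam radiation) after breast-conserving surgery over the
    patient's remaining lifetime. Converts organ radiation doses into
    pooled late-complication probabilities, incidence-weighted life
    expectancies and costs; simulates annual-cycle cohort trajectories
    with dwell-limited (tunnel) states and discounted cost and QALY
    streams; classifies dominance and computes cost per QALY, incremental
    ratios and net monetary benefit at a willingness-to-pay threshold;
    and runs one-way sensitivity sweeps, tornado orderings and
    net-monetary-benefit crossover (threshold) searches, plus
    budget-impact arithmetic. Results are tibbles with broom-style
    tidy()/glance() methods and ggplot2 autoplot() figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
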