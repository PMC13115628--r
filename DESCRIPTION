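Package: lbcroi
Title: Markov Cohort Cost-Effectiveness and Return on Investment for
    Lifestyle and Behavioral Care Programs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annual-cycle cohort state-transition (Markov) model of
    cardiometabolic disease progression for economic evaluation of
    lifestyle and behavioral care programs from an employer or payer
    perspective.  Compares an intervention arm against a modeled
    usual-care arm and reports discounted direct medical costs,
    quality-adjusted life years, net savings and return on investment,
    with deterministic (tornado) and probabilistic (Monte Carlo)
    sensitivity analysis over beta, gamma and lognormal parameter
    distributions.  Ships fully parameterized default state, transition
    and life tables plus a synthetic-scenario generator, so every
    analysis is runnable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
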