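Package: delaychoice
Title: Hyperbolic Discounting Models for Episodic Intertemporal Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying intertemporal choice between observed and
    mentally simulated rewards. Generates factorial episodic and monetary
    choice-task schedules, simulates synthetic agent cohorts (healthy,
    elderly control, Alzheimer-like and behavioral-variant FTD-like
    phenotypes) whose choices follow a hyperbolic-discounting plus softmax
    model, fits the model by maximum likelihood, and provides the
    accompanying statistics: bisquare robust regression, per-subject slope
    tests, quantile-binned summaries, intersubject interaction GLMs,
    mixed-design group-by-condition ANOVA, and a bootstrap mediation
    analysis linking grey-matter density, functional activation and choice
    impulsivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
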