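Package: mepsim
Title: Simulating Measurement Error in Predictive Models of Diet-Health Relationships
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying how classical and Box-Cox
    structured measurement error in replicate dietary intake measurements
    (such as repeated 24-hour recalls) degrades the predictive performance
    of regression models and fully connected neural networks. Provides the
    error and outcome generating models, three replicate-preparation
    strategies (averaging, concatenation, transform-then-average), closed
    form variance-reduction theory with Monte Carlo verifiers, a seeded
    multilayer-perceptron trainer, and orchestration for four simulation
    experiments covering transformations, the sample-size versus
    replicate-count trade-off, nonlinear outcomes, and binary prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    pracma,
    stats,
    utils,
    tibble,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
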