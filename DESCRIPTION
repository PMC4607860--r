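Package: satdyn
Title: Simulation and Analysis of Multiple-Response Speed-Accuracy Tradeoff Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditory multiple-response speed-accuracy tradeoff
    (MR-SAT) studies of memory retrieval during sentence comprehension.
    Simulates tone-paced response streams under an equal-variance
    signal-detection model with latent exponential d-prime growth, scores
    key-press streams into d-prime time courses, fits hierarchically nested
    exponential approach-to-limit models with a multi-start bounded optimizer
    portfolio, compares nested models by parameter-adjusted R-squared across
    participants, and runs group-level mixed-model inference on asymptote,
    rate, and intercept parameters with an optional reading-ability covariate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
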