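Package: attritionABC
Title: Likelihood-Free Inference for Stochastic Lanchester Attrition Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits stochastic Lanchester attrition models to battle casualty
    records by rejection approximate Bayesian computation (ABC), with
    Bayes-factor model selection over four competing laws (linear, squared,
    logarithmic and a fatigue variant of the logarithmic law). Per-battle
    fighting-value odds are drawn from a gamma distribution parameterized by
    its mean and standard deviation, battles are simulated until historical
    casualty totals are reached, and parameter draws are accepted by distance
    quantile. Includes a synthetic battle-record generator with known ground
    truth so parameter and model recovery can be verified without external
    data, posterior summary and model-comparison tables, and base graphics
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
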