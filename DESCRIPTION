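Package: painbayes
Title: Bayesian Observer Modelling of Placebo Analgesia Under
    Instrumental Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing placebo analgesia induced by instrumental
    conditioning in a "medical trust game": simulation of the conditioning
    and test sessions, calibration of the logarithmic stimulus-to-sensation
    mapping, Gaussian prior-likelihood fusion of expected and felt pain,
    Markov chain Monte Carlo estimation of per-participant condition priors
    from conditioning trials, prediction of test-session pain ratings, and
    comparison against a linear-regression baseline with RMSE and a
    prediction-error BIC, together with the behavioural statistics of the
    paradigm (choice probabilities, condition summaries, paired t-tests,
    predicted-versus-actual correlations).
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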