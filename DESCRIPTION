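Package: groupbms
Title: Group Bayesian Model Selection, Family Inference and Model Averaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-level Bayesian model selection over large discrete model
    spaces from per-subject log model evidences. Implements fixed-effects
    inference (group Bayes factors, posterior model probabilities),
    random-effects inference on population model frequencies via Gibbs
    sampling of a Dirichlet-multinomial generative model (with a variational
    alternative), family-level inference with unequal family sizes and
    family-uniform priors, exceedance probabilities, and Bayesian model
    averaging of parameter posteriors within families using Occam's-window
    mixture sampling. Includes enumeration of dynamic-causal-model style
    model spaces (input patterns crossed with modulation patterns) and
    synthetic-data generators for populations with known model frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
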