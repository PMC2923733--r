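Package: scrdcm
Title: Dynamic Causal Modelling of Skin Conductance Responses
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A generative (forward) model of skin conductance generation from
    parameterised sudomotor nerve activity, together with its Bayesian (MAP)
    inversion for trial-by-trial estimation of anticipatory, evoked and
    spontaneous electrodermal responses in event-related designs such as fear
    conditioning. Includes the conventional benchmark estimators (peak
    scoring within the anticipation window, convolution GLMs with canonical
    response functions and their derivatives), a statistical validation layer
    (BIC-based Bayes factors, condition-prediction GLMs, Rescorla-Wagner
    learning-rate fits), signal preprocessing (zero-phase Butterworth
    band-pass, downsampling, z-transform), response-function estimation by
    PCA of event-locked epochs, and a fully ground-truthed synthetic
    conditioning-experiment simulator.
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
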