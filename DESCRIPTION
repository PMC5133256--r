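Package: initempo
Title: Temporal Predictability of Syllable-Nucleus Timing in Speech
Version: 0.1.0
Authors@R:
    person("initempo", "maintainers", email = "initempo@example.org",
           role = c("aut", "cre"))
Description: Quantifies how predictable the timing of syllable nuclei is in
    annotated speech, at three structural levels: order-0 distributional
    metrics (a Kolmogorov-Smirnov non-uniformity statistic against a
    moment-matched normal, and an inter-nucleus-interval nPVI), an order-1
    Bayesian ideal-learner analysis (conjugate normal-inverse-chi-squared
    posterior, Student-t posterior predictive, differential-entropy
    predictability scores), and higher-order ARMA(p,d,q) multi-model
    inference with AICc and Akaike weights over log-interval series with
    break-masked missing values and an intensity-difference external
    regressor. Includes Praat TextGrid and tab-separated annotation I/O,
    dynamic-time-warping inter-annotator agreement, a synthetic corpus
    generator with recorded ground truth, and a per-language/corpus
    reporting pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
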