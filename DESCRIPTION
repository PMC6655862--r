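Package: infocap
Title: Information Capacity and Input Discrimination for Single-Cell
    Signaling Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates mutual information, channel capacity and pairwise
    probabilities of correct discrimination for systems with a discrete
    input (stimulus level) and a continuous, possibly high-dimensional
    output (e.g. single-cell signaling responses measured over time).
    The conditional input distribution is estimated by multinomial
    logistic regression, and capacity is obtained by an alternate
    maximization scheme in which the input distribution update has a
    closed form and the classifier is re-calibrated to a new prior by an
    intercept-only adjustment, so a single regression fit suffices.
    Includes synthetic channel generators with density-based numeric
    oracles (quadrature mutual information, discretized Blahut-Arimoto
    capacity, analytic Gaussian discrimination) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    nnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
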