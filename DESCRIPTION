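Package: nccpv
Title: Predictive Values and Confidence Intervals from Nested Case-Control Diagnostic Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates positive and negative predictive values (post-test
    probabilities) of a dichotomous diagnostic index test from a nested
    case-control sample, by weighting the sampled controls with the inverse
    sampling fraction. Provides six alternative confidence-interval
    estimators (naive and sampling-fraction-corrected Wald intervals, a
    stratified percentile bootstrap, delta-method intervals from
    sensitivity/specificity/prevalence on the probability and logit scales,
    and weighted logistic regression), together with a Monte-Carlo engine
    that draws cohorts from a source population, nests case-control samples
    inside them, and evaluates empirical coverage and mean interval width of
    each estimator. A command-line interface exposes estimation and
    simulation for scripted use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
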