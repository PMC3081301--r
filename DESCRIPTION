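Package: pi0bench
Title: Simulation Benchmark of Estimators of the Proportion of True Null Hypotheses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for estimating the proportion of true null hypotheses (pi0)
    from a vector of p-values, and for benchmarking such estimators by
    simulation. Implements five p-value-based pi0 estimators (beta-uniform
    mixture upper bound, LOESS-smoothed p-value spacing density minimum,
    monotone B-spline CDF derivative minimum, lambda-tail extrapolation via a
    smoothing spline, and the median-slope empirical-CDF estimator), a
    correlated two-condition gene-expression simulator with block
    equicorrelation, exact power and proportion-of-false-positives
    calculations for the pooled-variance two-sample t-test, and a replicated
    benchmark over the (pi0, rho) parameter space with mean-absolute-error
    summaries, paired t-test comparisons and best-method region
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
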