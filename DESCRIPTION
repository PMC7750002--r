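Package: benchdose
Title: Benchmark Dose and BMDL Estimation for Dose-Response Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits parametric dose-response models (log-logistic, log-normal,
    Weibull, exponential decay, multistage) to binomial, count, and continuous
    data by maximum likelihood and derives benchmark doses (BMD) and their
    one-sided lower confidence limits (BMDL) under the additional, excess,
    hybrid, added, extra, relative, and point definitions.  Uncertainty
    methods include delta-method Wald intervals on the natural or log scale,
    inverse regression on the confidence band, nonparametric, parametric, and
    semiparametric bootstrap, and sandwich (robust) covariance estimation with
    optional clustering.  Model-averaged BMD/BMDL via AIC, BIC, or user
    weights supports both estimate averaging and curve averaging, with
    Buckland-type, weighted, and bootstrap BMDLs.  A nonparametric isotonic
    (pool-adjacent-violators) alternative and a two-step random-effects
    meta-analytic procedure for hierarchical designs are included, along with
    seeded synthetic-data generators for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    sandwich
Config/testthat/edition: 3
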