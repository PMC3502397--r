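Package: fractalmua
Title: Fractal Analysis of Multi-Unit Neural Activity Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detrended fluctuation analysis (DFA) of binned spike-count
    recordings from the suprachiasmatic nucleus and similar multi-unit
    preparations. Implements order-2 DFA with log-spaced scale grids,
    scaling-exponent fits, local-slope (crossover) profiles, power-law
    deviation testing, shuffle surrogates, missing-data down-sampling with
    simulation-based exponent adjustment, circadian and ultradian rhythm
    metrics, amplitude-threshold subpopulation selection, and a synthetic
    generator (fractional Gaussian noise by circulant embedding, 1/f^beta
    spectral synthesis, Brownian and in-vitro-like signals) for validating
    the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
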