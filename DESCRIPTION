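Package: rtdcca
Title: Real-Time Detrended Cross-Correlation Analysis of Long-Range
    Coupled Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: One-pass (streaming) estimation of detrended
    cross-correlation analysis (DCCA), detrended fluctuation analysis
    (DFA) and the detrended cross-correlation coefficient (DCCC) for
    pairs and arbitrary sets of simultaneously recorded signals, such
    as multichannel EEG. Per-scale helper-variable accumulators yield
    the detrended covariance of each window without storing the signal,
    so scaling functions and coefficients are emitted in real time over
    a circular analysis window. Includes two-pass offline reference
    implementations (sliding and non-overlapping window variants),
    scaling-exponent fitting, a mixed-correlated ARFIMA (mc-ARFIMA)
    generator for long-range cross-correlated test signals with
    white-noise and spike-artifact contamination, and evaluation
    drivers that measure streaming precision and robustness on
    simulated grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
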