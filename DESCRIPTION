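Package: ccdrand
Title: Randomization Tests and Power Simulation for Changing Criterion Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Randomization tests for single-case changing criterion designs
    (CCDs) using the mean absolute deviation of the measurements from their
    phase criterion levels as test statistic. Two randomization schemes are
    supported: phase-change-moment (PCM) randomization, which fixes the order
    of the criterion levels and randomizes the occasions at which the
    criterion changes subject to minimum and maximum phase lengths, and
    blocked-alternating-criterion (BAC) randomization, which fixes the phase
    boundaries and randomizes the order of the two criterion levels within
    consecutive blocks of two phases. Includes exact counting, systematic
    enumeration and uniform sampling of bounded integer compositions, a Monte
    Carlo engine for estimating type I error rates and statistical power under
    lag-one autocorrelated, criterion-proportional noise with optional
    mini-reversals, and effect-size summaries (eta-squared, paired-t R
    squared) for simulation result grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
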