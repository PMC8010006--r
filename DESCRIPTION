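Package: fareyscan
Title: Oscillatory Entrainment Analysis of Sequential Effects in Two-Choice
    Response Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models sequential dependencies in two-alternative forced-choice
    response times as mode-locking of two coupled oscillators (the two response
    fingers), using a discretized Haken-Kelso-Bunz circle map. Provides the
    map engine (Devil's staircase rotation numbers, bifurcation surfaces,
    circular means), the Farey/Stern-Brocot machinery that assigns every one-
    to five-trial stimulus history a mediant fraction, binary rank, and driving
    ratio, an overlapping-window trial-stream scanner with censorship rules and
    unique-error rates, the corresponding inferential battery (staircase
    correlations with F conversion, binary-rank Spearman tests, denominator
    regressions, paired history contrasts, partial r-squared decomposition),
    and a synthetic trial-stream generator for end-to-end parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
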