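Package: lickroc
Title: Censored First-Lick-Latency ROC Analysis for Visual Detection Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for head-fixed go/no-go visual detection
    behavior in which performance is scored from the temporal distribution
    of first-lick latencies. Implements the censored-latency ROC statistic
    (aROC) with Misses and Correct Rejections assigned a surrogate latency
    outside the response window, windowed signal-detection rates and
    d-prime with optimal response-window search, learning-curve
    aggregation with linear learning-rate fits and criterion detection,
    Weibull psychometric fitting of aROC against stimulus contrast with a
    silencing modulation index, and hyperbolic-ratio contrast-response
    fitting of collicular multi-unit activity with a depth-resolved
    silencing profile. A seeded synthetic-session generator reproduces
    the statistical structure of training cohorts (intact, cortico-fugal
    ablation and cortical-lesion groups) so every analysis can be
    exercised end to end without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
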