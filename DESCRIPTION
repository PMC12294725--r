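Package: baexposure
Title: Acute Dietary Exposure Assessment of Biogenic Amines in Foods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for acute dietary exposure assessment of biogenic amines
    (histamine, tyramine, putrescine, cadaverine, tryptamine) in food
    monitoring data. Provides descriptive statistics for left-censored
    concentration tables (detection rates, means and percentiles of
    detects), deterministic point assessment of worst-case exposure
    against an acute reference dose, maximum-likelihood fitting of
    lognormal concentration and consumption distributions, a discrete
    detect/non-detect mixture concentration model, Monte Carlo simulation
    of acute exposure with bootstrap percentile confidence intervals and
    exceedance probabilities, level-of-concern back-calculation, and a
    synthetic-data generator emulating left-censored monitoring surveys.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
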