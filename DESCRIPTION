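Package: flavrisk
Title: Quantification and Inhalation Risk Assessment of Flavoring Agents in Cigarettes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative workflow behind GC-MS/MS surveys of
    allergenic flavoring agents in cigarette parts (tobacco rod, filter tip,
    flavor capsules): instrument-level to per-cigarette content conversion,
    method-validation metrics (calibration linearity, signal-to-noise
    detection limits, recovery, relative standard deviation), left-censored
    data handling by limit-of-quantification substitution, inhalation
    exposure-concentration estimation, risk characterization ratios against
    derived no-effect levels (DNEL), nonparametric group comparisons
    (Kruskal-Wallis with Dunn-Bonferroni post hoc, Mann-Whitney U) and PCA
    fingerprinting, plus a seeded synthetic study generator that emulates a
    54-cigarette market survey for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
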