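Package: tomoqa
Title: Patient-Specific Tomotherapy QA: Gamma Analysis and TG-218 Process Control
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pre-treatment patient-specific quality assurance of
    helical tomotherapy deliveries: a 2D gamma-index engine (global and local
    normalization, low-dose threshold, continuous distance-to-agreement
    search), TG-218 clinic-specific action and tolerance limits built on
    individuals/moving-range statistics with bootstrap confidence intervals
    and periodic process monitoring, plan-complexity metrics (TTDF, leaf-open
    time descriptors), cohort statistics (Kruskal-Wallis with Bonferroni
    post-hoc comparisons, predictor screening and n-way ANOVA), and a
    synthetic-data generator that emulates the statistical structure of a
    clinical QA database so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
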