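Package: suppscreen
Title: Analysis of Chemical Suppression Screens in SDH-Loss Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing plate-reader chemical suppression screens
    built on the sulfur-scavenging growth assay of succinate dehydrogenase
    (SDH) loss yeast. Provides plate and well data models with CSV I/O,
    a synthetic-data generator with planted ground truth (growth curves,
    proteomes, metabolite panels), screening-window Z statistics with the
    single-well mock standard-deviation rule, multi-timepoint hit calling
    with formulation-based exclusions, percent-growth-change metrics with
    first-order error propagation, diauxic-shift detection, dose-response
    selectivity classification, differential protein abundance with dual
    significance thresholds and Venn partitioning, and
    succinate:2-ketoglutarate ratio analysis, together with the one- and
    two-way ANOVA, Tukey HSD, Welch t and Benjamini-Hochberg machinery
    the downstream comparisons use.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
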