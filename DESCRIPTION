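Package: cghcnv
Title: Targeted Array-CGH Copy Number Calling, Curation and Trio Inheritance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, quality control, segmentation and downstream
    interpretation of custom targeted array-CGH copy-number profiles, built
    around Hirschsprung-disease candidate-region designs. Provides a
    synthetic-profile generator with planted copy-number variants, derivative
    log ratio spread (DLRS) quality control, maximal interval-score
    segmentation at a configurable threshold, rule-based call curation
    (probe-count and mean-absolute-log2-ratio filters, split/merge rules,
    visual-inspection triage emulation, replicate concordance), consistency
    matching against population CNV databases with Fisher / Yates chi-square
    frequency tests, a "true variant" classifier with cohort summaries, and
    trio-based parental-origin assignment with exact binomial transmission-bias
    tests and Clopper-Pearson confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
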