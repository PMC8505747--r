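Package: precisionMMN
Title: Precision-Manipulated Oddball Paradigms and Cluster-Based ERP
    Correlation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the precision (stability) of an auditory
    context modulates deviance-detection potentials such as the mismatch
    negativity. Provides generators for probability-graded oddball tone
    sequences built from microsequences, a simulator for epoched multichannel
    ERP data with planted precision effects, a preprocessing pipeline
    (baseline correction, joint-probability epoch rejection, zero-phase
    Butterworth low-pass filtering, difference waves), and a mass-univariate
    two-dimensional (time by electrode) cluster-based permutation correlation
    analysis using the weighted cluster mass statistic, with confirmatory
    Kruskal-Wallis and Tukey-Kramer window tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    igraph,
    yaml
Config/testthat/edition: 3
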