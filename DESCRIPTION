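Package: dynanet
Title: Dynamic Network Analysis of Inflammatory Mediator Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers interval-wise signed correlation networks from
    multiplexed inflammatory-mediator (cytokine/chemokine) concentrations
    measured across tissue compartments and time in terminally sampled
    cohorts. Implements the Dynamic Network Analysis (DyNA) procedure:
    mediators must differ from the 0 h control group (Mann-Whitney U) before
    they may carry edges, edges connect mediator pairs whose Pearson
    correlation within a time interval reaches an absolute threshold, and
    per-interval network complexity and total-connection summaries compare
    experimental groups. Also provides trapezoidal area-under-curve
    trajectory summaries with between-strain ratios, windowed Spearman
    correlations with percentile-bootstrap confidence intervals, a
    synthetic-cohort generator with planted correlation structure for
    validation by parameter recovery, and a reproducible end-to-end
    pipeline with network export to edge-list and GraphML formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    igraph,
    jsonlite,
    pracma,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
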