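Package: dcenet
Title: Within-Individual Time-Series Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed co-expression networks from short time-series
    expression studies with repeated measures per individual. Correlations
    are computed within each individual's time series first and aggregated
    across a group with a support-fraction and sign-consistency edge rule,
    which keeps the high inter-individual variability of human cohorts from
    washing out group-level co-expression. Includes a Y-chromosome noise
    floor background filter, paired differential expression with an
    empirical-Bayes moderated t and Storey q-values, Frobenius-norm
    individual-variability diagnostics, sign-consistent overlap networks
    between two groups, greedy-modularity community clustering,
    hypergeometric over-representation analysis against GMT gene sets, and
    a synthetic study generator with planted co-expression modules and
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    yaml,
    optparse
Config/testthat/edition: 3
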