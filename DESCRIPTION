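Package: mcoFrontier
Title: Pareto-Efficient Frontier Analysis for Differential Gene Expression
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies highly differentially expressed genes as the
    Pareto-efficient frontier of a multiple-criteria optimization problem.
    Each gene is scored on two to five conflicting performance measures
    (absolute differences of group means or medians between conditions,
    transformed to minimization direction) and the nondominated set is
    found with an exact pairwise penalty-matrix scheme: per-criterion
    comparison matrices are accumulated, penalized, and row-summed so that
    frontier membership reduces to an integer threshold test. Includes
    tournament partitioning for large probe sets, successive frontier
    peeling, a reader for GEO SOFT/GDS expression files with sample-subset
    annotations, a synthetic two-group data generator with planted
    large-effect genes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
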