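Package: cyclostat
Title: Cyclo-Stationary mRNA and Protein Copy-Number Distributions for
    Random Cell-Division Times
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Exact series computation of cyclo-stationary copy-number
    distributions of mRNA and bursty protein in growing and dividing cells,
    for arbitrary uncorrelated random division-time distributions. Implements
    the generating-function coefficient recursions and their inversion to
    probability mass functions (with quadruple-precision arithmetic and Borel
    summation for slowly converging series), cell-age-resolved and
    age-averaged distributions under the Powell age weight, closed-form
    coefficient-of-variation formulas with an additive decomposition of
    protein noise into binomial-partitioning, division-time and
    gene-expression components, and an independent kinetic Monte Carlo
    lineage simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
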