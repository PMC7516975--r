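Package: ucurve
Title: U-Curve Feature Selection on Boolean Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Optimal and suboptimal feature selection by minimisation of
    cost functions that decompose into U-shaped curves along the chains of
    the Boolean lattice of feature subsets. Implements the Parallel U-Curve
    Search (PUCS) algorithm, which partitions the lattice into outer and
    inner Boolean lattices and prunes intervals of the search space during
    a walk on the outer lattice, together with exhaustive search, U-curve
    branch-and-bound, and sequential (floating) forward selection as base
    algorithms. Ships the penalized mean conditional entropy criterion for
    discrete labelled samples, a subset-sum reduction for generating hard
    synthetic instances, an oscillation statistic measuring departures from
    the U-curve assumption, and a benchmark harness with tidy reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
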