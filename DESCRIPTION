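Package: patchboot
Title: Fast Patchwork Bootstrap Inference for Network Degree Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric bootstrap confidence intervals for functions of a
    network degree distribution (degree probabilities f(k) and the mean degree)
    from a single partially observed graph. Patches (ego networks) are grown
    around randomly sampled seeds by labeled snowball sampling with multiple
    inclusions, vertices are resampled within patches with inverse-degree
    weights, and Efron percentile intervals are read from the bootstrap
    distribution. Patch size (the seed-wave combination) is chosen by a
    data-driven cross-validation procedure that reuses one maximal snowball
    sample. Includes parametric degree laws (zero-truncated Poisson,
    polylogarithmic), configuration-model graph generation with rewiring to a
    simple graph, simple-random-sampling competitor intervals, and a Monte
    Carlo harness for coverage and sharpness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
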