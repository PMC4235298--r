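Package: herbdiv
Title: Functional and Phylogenetic Diversity Effects on Sapling Herbivory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking individual-level insect herbivory on woody-plant
    saplings to the functional and phylogenetic diversity of the surrounding
    community. Computes abundance-weighted community metrics (community-weighted
    mean traits, single-trait and multivariate Rao's quadratic entropy,
    phylogenetic Rao's Q and focal-species dispersion analogous to mean pairwise
    distance), calibrates visually estimated leaf-damage classes against scanned
    leaves, screens predictors for collinearity, and fits binomial generalized
    linear mixed models with crossed random intercepts and an observation-level
    term by Laplace approximation, with AICc-based backward simplification and
    multimodel comparison. Includes a synthetic-study generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
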