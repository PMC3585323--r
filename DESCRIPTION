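Package: dyadmaxent
Title: Maximum-Entropy Joint Modeling of Paired Directed Binary Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jointly models two directed binary networks observed on a shared
    node set by encoding every ordered node pair as a 4-bit linkage vector,
    fitting a mean-field independence null from the two network densities, and
    sequentially accommodating constraint functions (within-network
    reciprocity, cross-network direction opposition, cross-network presence
    covariance, or user-supplied functions on the 16 linkage states) by
    maximum-entropy exponential tilting. Each constraint contributes one
    Lagrange multiplier, solved by moment matching; fitting stops when the
    10-class chi-squared statistic drops below a chi-squared critical value.
    Includes a dyad-level synthetic network generator for parameter-recovery
    experiments, Yates-corrected contingency and two-proportion tests for
    comparing edge composition across conditions, and tidy accessors and plots
    for fitted models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    igraph,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
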