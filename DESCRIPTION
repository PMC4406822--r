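Package: priorbf
Title: Bayes Factors with Uncertainty in the Effect-Size Prior Variance for SNP Fine-Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Approximate Bayes factors for single-SNP case-control association
    that place a probability distribution on the variance W of the zero-mean
    normal prior on the log odds ratio, instead of fixing W as the Wakefield
    approximation requires. Implements the power, exponential, hybrid and
    reciprocal prior families on W with normalized densities, distribution
    functions, moments and sampling; the corresponding prior-averaged Bayes
    factors with closed-form, quadrature and Monte-Carlo evaluation paths;
    elicitation of hyperparameters from expert odds-ratio probability
    intervals by quantile matching; an LD-structured case-control genotype
    simulator; and threshold-averaged ROC evaluation of SNP filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
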