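Package: hbramp
Title: Position-Dependent Hydrogen-Bond Profiling and Ramp Modeling of ORFeomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles the per-codon hydrogen-bond content of coding-sequence
    collections (ORFeomes) position by position from the 5' end, computes
    positional codon-usage metrics (RSCU, CAI weights, tAI weights, mRNA
    unpaired-probability adapter), fits uniform, linear and bounded
    exponential ramp models to positional profiles with AIC/BIC model
    selection, and tests for selection on hydrogen bonding against a
    synonymous codon-shuffling null model (z-squared and chi-gram
    statistics). Includes group-wise comparisons by operon position and
    expression strata, and a synthetic ORFeome generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    minpack.lm,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
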