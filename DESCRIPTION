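Package: msclassify
Title: Decision-Tree Classification of Secondary Progressive Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assign the current multiple sclerosis phenotype
    (relapsing-remitting versus secondary progressive) from a patient's most
    recent EDSS score and age.  Implements a published nine-leaf decision-tree
    classifier as a deterministic rule table, a from-scratch CART trainer with
    cost-complexity pruning and cross-validated complexity-parameter selection,
    an adapted MSBase confirmed-EDSS-progression detector for longitudinal
    visit records, diagnostic-accuracy metrics with binomial confidence
    intervals, Kaplan-Meier comparison of time to secondary progression across
    labelling methods, and a synthetic registry-cohort simulator so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
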