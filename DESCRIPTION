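Package: uniclock
Title: Universal Pan-Mammalian Epigenetic Clocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Build and evaluate universal DNA methylation age estimators that
    apply across mammalian species and tissues. Implements the three clock
    outcome transformations (log age, double-logarithmic relative age, and
    log-linear adult age) together with their exact inverses, elastic-net
    clock training on CpG beta values with species- and tissue-stratified
    cross-validation (leave-one-fraction-out and leave-one-species-out),
    epigenetic age acceleration and group comparisons, a two-step unweighted
    Stouffer meta-analysis for cross-species epigenome-wide association
    studies of age, one-sided hypergeometric annotation enrichment, and a
    seeded generator of multi-species synthetic methylomes with planted
    age signal for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
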