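Package: emargin
Title: Feature Gene Extraction by Error-Margin Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Margin-based feature gene extraction for two-class gene
    expression data. Genes are ranked by two-sample t-test relevance, a
    leave-one-out error-margin curve is built over nested subsets of the
    most relevant genes using linear maximum-margin classifiers, and the
    number of feature genes is estimated as the critical point of a
    continuity-constrained two-segment polynomial least-squares fit to
    that curve. Includes a synthetic expression benchmark generator,
    a t-test filter baseline, and benchmark protocols reporting selected
    set sizes, hitting/redundancy rates and validation accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
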