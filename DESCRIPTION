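Package: bicsim
Title: Synthetic Benchmark Generation for Biclustering Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic numeric, symbolic, and mixed-type data
    matrices with planted ground-truth biclusters for the normative
    evaluation of biclustering algorithms. Supports constant, additive,
    multiplicative and order-preserving coherencies on rows and columns,
    plaid composition of overlapping biclusters (additive, multiplicative
    or interpolated), temporally contiguous biclusters with monotone time
    profiles, four background distributions, and controlled injection of
    missing values, bounded noise and out-of-threshold errors. Ships named
    preset configurations spanning illustrative, baseline and
    domain-mimicking scenarios, writes dataset/solution/settings bundles
    (TSV, JSON, TXT), and provides the virtual-error internal homogeneity
    metric and an element-level Jaccard score for solution comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
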