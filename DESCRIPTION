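Package: mdselect
Title: Robust Hybrid Gene Selection with the Md Score
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Filter-based feature selection for two-class high-dimensional
    expression data. Implements the hybrid Md score (per-gene signal-to-noise
    ratio divided by the Mood's median test P-value) alongside the classical
    SNR, Fisher-score and Wilcoxon rank-sum filters, top-k gene selection,
    and a repeated stratified cross-validation harness estimating Random
    Forest and k-nearest-neighbour misclassification error for the selected
    subsets. Includes a seeded synthetic-data generator with planted
    informative genes, heavy-tailed noise and outlier contamination, delimited
    text loaders/writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    randomForest,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
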