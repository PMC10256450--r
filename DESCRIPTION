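Package: csadt
Title: Crow Search Algorithm Wrapper Feature Selection with a Decision-Tree Fitness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Wrapper feature selection for binary classification built on the
    crow search algorithm (CSA), a population metaheuristic in which each agent
    keeps a memory of its best-found position and either follows another
    agent's memory or relocates at random, gated by an awareness probability.
    Continuous crow positions are mapped to binary feature masks through a
    sigmoid transfer function with a random threshold, and each mask is scored
    by a weighted sum of a decision-tree error rate and the selected-feature
    fraction. The package provides min-max normalization, the continuous CSA
    optimizer, the sigmoid binary adapter, the wrapper fitness, confusion-matrix
    metrics (accuracy, precision, recall, F1), a synthetic-data generator with
    known informative structure, delimited-text I/O, and a command-line
    interface, all behind a single model-fitting entry point csadt().
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    nnet,
    randomForest,
    class,
    optparse,
    withr
Config/testthat/edition: 3
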