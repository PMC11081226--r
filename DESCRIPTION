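Package: MGAselect
Title: Matrix-Structured Genetic Algorithm Feature Selection for
    High-Dimensional Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Wrapper and filter feature selection for high-dimensional,
    low-sample-count labelled expression-style matrices. Provides a
    matrix-structured (grid) genetic algorithm with diagonally dominant
    selection, a GA-KNN wrapper that evolves per-feature weight chromosomes
    under five encoding schemes scored by k-nearest-neighbour validation
    accuracy, KNN missing-value imputation with co-observation-masked
    taxicab distances, chi-square relevance filtering, and genetic-
    programming feature construction with protected arithmetic. Includes
    seeded synthetic-data generators with planted informative and redundant
    features, an experiment protocol runner, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
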