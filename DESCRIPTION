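Package: gawcc
Title: Two-Stage GA + WCC Wrapper Feature Selection with SVM Fitness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Wrapper feature and gene selection for omics-scale tabular data
    using a two-stage metaheuristic: a variable-length genetic algorithm
    whose terminal population seeds a World Competitive Contests (WCC)
    optimizer with attacking, transferring and passing operators and greedy
    accept-if-improved moves.  Candidate feature subsets are scored by
    cross-validated support-vector-machine performance.  Also provides five
    classical filter baselines (Pearson correlation, Laplacian score,
    entropy / information gain, mutual information, Fisher score) with top-k
    truncation, a filter-then-wrapper variant, a multi-execution comparison
    protocol, and a synthetic benchmark generator with planted informative,
    neutral and misleading features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    foreign,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
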