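Package: hmtree
Title: Hidden Markov Tree Models for Gene Ontology Structured Hypothesis Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests many logically nested gene-set hypotheses arranged on a
    Gene Ontology style directed acyclic graph. The DAG is deterministically
    transformed into a tree of disjointly carved gene sets, node-level
    p-values from any multivariate gene-set test are modelled with a
    two-state hidden Markov tree (beta-uniform mixture emissions), parameters
    are estimated by expectation maximization with random restarts and
    deterministic annealing, and exact belief propagation (the
    upward-downward algorithm) yields a posterior probability of
    differential expression (PDE) for every node of the original DAG,
    together with a false discovery rate estimate for any rejection set.
    Includes a model-faithful synthetic-data generator and brute-force
    enumeration oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
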