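Package: semflow
Title: Knowledge-Graph-Backed Composition of Machine-Learning Microservices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A registry, planner and policy store for semantically described
    machine-learning microservices. Services are registered with a
    nine-parameter ontology (typed input/output ports among them) into a
    partitioned triple store; a planner enumerates I/O-compatible service
    chains from a task's input kind to its desired output kind; an executor
    runs chains on tabular or single-cell count payloads; outcomes are
    recorded as policies with a 1/n-per-step reward rule that drives
    candidate ranking, transfer reuse of recorded workflows on new
    datasets, and reuse of feature-selection facts across identical table
    schemas. Ships built-in services (CSV loading, stratified splitting,
    quality control, normalisation, regularised logistic classification,
    recursive feature elimination with cross-validation, PCA embedding,
    k-means and graph clustering) and synthetic-data generators for
    clinical-style labelled tables and planted-cluster count matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    glmnet,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
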