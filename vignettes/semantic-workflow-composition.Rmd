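---
title: "Semantic workflow composition with a knowledge-graph policy store"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic workflow composition with a knowledge-graph policy store}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semflow)
```

## The model

`semflow` automates the assembly of machine-learning pipelines from
registered microservices. Three ideas carry the design:

1. **Typed service descriptions.** A microservice is opaque except for its
   nine-parameter registration record, of which the typed ports matter most:
   one primary input data kind and exactly one output data kind, both drawn
   from a frozen controlled vocabulary (`data_kinds()`). Composition is then
   pure type-checking: service *B* may follow service *A* iff *A*'s output
   kind equals *B*'s input kind. Restricting services to one primary input
   makes every admissible pipeline a linear chain, which keeps planning
   complete and cheap; fan-in/multimodal composition is a deliberate
   non-goal.

2. **Tasks as contexts.** A task is keyed by `(input kind, domain, desired
   output kind, dataset signature)`. The signature records column names (in
   order) and modality but deliberately ignores the row count: two draws
   from the same schema are the *same* task (`EXACT`), while the same
   request on a different schema is `TRANSFERABLE`. Domain comparison is
   case-insensitive exact string equality — free-text similarity is out of
   scope, and exactness never reuses knowledge across genuinely different
   domains.

3. **Outcomes as rewards.** Every run is recorded as a policy with binary
   state. A successful \(n\)-step workflow distributes total reward 1
   uniformly: each step earns \(1/n\). A failed run pays the \(m\) steps
   that completed \(1/m\) each — partial credit makes services that reliably
   work accumulate priority even out of failed attempts. Rewards add across
   records with no decay; a service's cumulative reward is the second
   ranking key (after chain length) when several candidate workflows exist.
   We read the failure rule as the mirror image of the success rule because
   the recorded failure configuration (three completed steps, three rewards)
   matches exactly that reading.

## Planning

The planner is depth-first enumeration over the digraph whose nodes are data
kinds and whose edges are services, bounded by `max_depth` (default 8,
generous for linear analysis pipelines) and by the no-repeated-service rule.
It returns *every* admissible simple chain, including ones that pass through
the goal kind and reach it again; completeness is tested against an
independent breadth-first enumerator on randomized registries. Ranking is a
total order — `(length ascending, cumulative service reward descending,
lexicographic step tuple)` — so results are deterministic and
`rank(rank(x)) == rank(x)`. When a single service solves the task outright
it simply ranks first by length; no special case is needed.

User preferences pin a pipeline *stage*, identified by the data kind that
stage produces, to a named service. A candidate survives only if it contains
that stage and agrees with the pin. With three embedders and two clusterers
registered, pinning the embedding stage to UMAP leaves exactly the two
UMAP-prefixed chains.

## Execution and reuse

Execution is local and in-process: invoke paths of the form `builtin:<name>`
resolve to registered callables; URI paths are stored but refused at run
time. A failing step never throws — the trace records succeeded / failed /
skipped statuses per step (statuses use 1-based indices, so a chain whose
fourth stage breaks reports `failure_index = 4` with three succeeded steps).
One seed is threaded to every stochastic stage, making replays
reproducible.

Reuse is tiered by context match level:

- `EXACT` success hit: the persisted solution (content-addressed directory
  holding the fitted artifact and a JSON manifest) is loaded; neither the
  planner nor the executor runs.
- `TRANSFERABLE` success hit: the recorded workflow structure is re-executed
  on the new payload — every stage fully retrained — and a *new* policy is
  written for the new context. The planner is provably not invoked
  (`planner_call_count()` is observable).
- World-knowledge reuse: a successful optimisation stores the selected
  feature subset keyed by the exact ordered column-name schema. A later task
  with an identical schema has its elimination stage replaced by a
  projection onto the stored subset (the classifier is still retrained —
  skipping retraining would silently assume the new sample resembles the
  old one). Exact ordered schema equality is the strictest reading; it
  never reuses features across semantically different datasets at the cost
  of missing harmless reorderings.

## The knowledge graph

All knowledge lives in one triple store with four fixed partitions. Two
representation choices favour determinism over expressiveness: identifiers
live under a single project namespace with percent-encoded local names, so
arbitrary strings (column names with spaces, quotes, newlines) survive
serialisation; and partition membership is encoded with a reserved
`inPartition` marker predicate rather than named-graph syntax, so plain
N-Triples suffices and `parse(serialize(s)) == s` holds exactly. Numeric
literals are written with 17 significant digits, which round-trips IEEE
doubles bit-for-bit. Literals are typed string / number / boolean only; no
language tags. There is no SPARQL engine — the reasoning the framework
needs is typed pattern matching (`ks_match`), which is tested against a
brute-force scan.

## Built-in services and their parameters

| Service | Parameter | Default | Why |
|---|---|---|---|
| `data_splitter` | `ratio` | 0.8 | conventional 80/20 stratified split |
| `counts_qc` | `depth_percentile` | 5 | common low-depth cell cut |
| `counts_qc` | `min_cells` | 3 | drop genes detected in < 3 cells |
| `classifier_pipeline` | `lambda` | 0.01 | mild ridge penalty; keeps separable fits finite and importances defined |
| `rfecv_optimizer` | `folds` | 5 | standard k-fold CV |
| `pca_embedder` | `dims` | min(10, p−1) | enough components for cluster geometry |
| `kmeans_cluster` | `k` | 3 | matches the three-population default fixture; always overridable per run |
| `louvain_cluster` | `neighbors` | 15 | usual kNN-graph neighbourhood size |

The classifier family is ridge-penalised logistic regression (`glmnet`,
fixed small λ): linear, fast, deterministic, and its absolute standardised
coefficients give the elimination criterion a clean meaning. The RFE-CV
loop is authored here because its protocol is pinned down precisely — score
the current subset by stratified k-fold mean CV accuracy, drop the feature
with smallest importance magnitude, record the full curve from *p* features
down to 1, select the size with maximal mean CV accuracy breaking ties
toward fewer features, refit on the full training partition. Graph
clustering buys igraph's greedy modularity maximisation on a symmetrised
kNN graph; k-means is `stats::kmeans` with seeded multi-start. t-SNE and
UMAP register as optional plug-in services that delegate to `Rtsne`/`uwot`
when installed and fail with a clear message otherwise; PCA and greedy
modularity are the always-available stand-ins, so both scenario pipelines
run with no optional dependency.

One port-kind decision deserves a note: the optimisation stage consumes the
*fitted classification model* (which carries its training split along)
rather than the split itself. This makes the minimal tabular chain
load → split → classify → optimise, i.e. the four-stage pipeline, rather
than allowing a degenerate three-stage shortcut around the classifier.
Similarly the single-cell stages use stage-distinct kinds
(`count_matrix` → `qc_count_matrix` → `normalized_matrix` → `embedding` →
`cluster_labels`) so the minimal clustering chain has exactly five stages —
the type system encodes the methodology.

## What the synthetic generators emulate — and what they don't

`make_classification_table()` draws independent standard-normal features
and Bernoulli labels from a logistic model on the informative features
only. The logistic data-generating model is chosen to match the linear
classifier family, so parameter-recovery tests are well-posed: under the
default study conditions (n = 500, five informative features with effects
1.5–0.8, ten noise features) the elimination stage should retain the
planted set, and does in ≥ 95% of seeded runs. Real clinical tables have
correlated, non-Gaussian, missing-valued features; passing these tests
shows the machinery is correct, not that any particular clinical accuracy
is reproduced. The headline accuracies reported for real heart-disease and
Parkinson data are computed on datasets this package does not ship and are
explicitly out of scope.

`make_heartlike_table()` (default 335 rows, matching the scenario's input
size) reproduces the 14-column clinical schema and value encodings, with
signal planted only in the eight features the scenario singles out (`sex`,
`cp`, `thalach`, `exang`, `oldpeak`, `slope`, `ca`, `thal`) — a qualitative
check that feature selection can find a designated subset, not a clinical
result. `make_count_matrix()` (default 200 cells × 500 genes, three equal
populations with 40-gene marker blocks at 6× weight, depths 2000–5000)
plants 5% of cells at depths of 20–60, far below the QC percentile, so the
planted set and the QC-removed set coincide exactly. It does not simulate
doublets, ambient RNA or batch effects.

## Numerical choices and degenerate inputs

- Reward exactness: step rewards are stored as IEEE doubles of `1/n`; sums
  are checked to `< 1e-12`.
- Ties: rank ties break lexicographically on the step tuple; RFE curve ties
  break toward fewer features; elimination ties drop the first-listed
  minimal-importance feature; continuous updates break reward ties toward
  the most recent policy.
- Degenerate inputs are rejected with informative errors: empty datasets,
  single-class splits, zero-variance features reaching normalisation,
  `k` exceeding the point count, folds exceeding the smallest class,
  everything filtered by QC.
- A planning failure is itself recorded as a policy (state 0, empty
  workflow, no rewards), so the knowledge store grows on every run and
  administrators can see which capability is missing.

## Problem sizes

The test suite and acceptance script exercise: randomized triple spaces up
to 500 triples; randomized registries of ≤ 8 services over ≤ 4 data kinds
(100 replicates against brute-force enumeration); 200 randomized reward
records; 20 seeded RFE runs at n = 500; and one 300-cell, 500-gene
clustering pipeline. These sizes were chosen to make every property
observable at high power while keeping a full run in tens of seconds.

## Known limitations

- Linear chains only; no fan-in, branching, or cross-modality conversion.
- Domain matching is exact; no semantic similarity.
- Policy rewards are additive with no decay or exploration — this is
  bookkeeping that biases ranking, not a full reinforcement-learning
  treatment.
- Remote services are registrable but never executed.
- The "human feedback" channel is a numeric reward adjustment whose
  semantics are user-defined.
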