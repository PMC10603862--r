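#' @title Default service environment
#'
#' @description Functions that initialise a knowledge space with the
#' framework's default services — three groups: data processing, ML, and
#' RFE-CV optimisation, nine descriptors in all — and the extended registry
#' for the single-cell clustering scenario (four extra services: count
#' loading, t-SNE and UMAP embedding, graph clustering).
#'
#' @name default_registry
NULL

.builtin_record <- function(name, description, category, in_kind, out_kind,
                            deps = list()) {
  list(name = name, description = description, framework = "R",
       dependencies = deps,
       inputs = list(port("input", in_kind)),
       outputs = list(port("output", out_kind)),
       category = category, license = "MIT",
       invoke_path = paste0("builtin:", name))
}

.builtin_callables <- function() {
  list(
    csv_loader          = svc_csv_load,
    counts_loader       = svc_load_counts,
    data_splitter       = svc_split,
    table_qc            = svc_table_qc,
    table_normalizer    = svc_table_normalize,
    counts_qc           = svc_counts_qc,
    counts_normalizer   = svc_counts_normalize,
    classifier_pipeline = svc_classify,
    rfecv_optimizer     = svc_optimize,
    feature_projector   = svc_feature_project,
    pca_embedder        = svc_embed_pca,
    tsne_embedder       = svc_embed_tsne,
    umap_embedder       = svc_embed_umap,
    kmeans_cluster      = svc_cluster_kmeans,
    louvain_cluster     = svc_cluster_graph)
}

.register_builtin_callables <- function() {
  cbs <- .builtin_callables()
  for (nm in names(cbs)) register_callable(paste0("builtin:", nm), cbs[[nm]])
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  .register_builtin_callables()
}

#' Registration records of the default services
#'
#' @return Named list of the nine default registration records, grouped as
#'   data processing (CSV loading, splitting, table QC, counts QC, counts
#'   normalisation), ML (PCA embedding, k-means clustering, classification)
#'   and RFE-CV optimisation.
#' @export
default_service_records <- function() {
  dp <- "data processing"
  recs <- list(
    .builtin_record("csv_loader",
      "Load a labelled CSV table into a typed data frame", dp,
      "csv_path", "labeled_table",
      deps = list(dependency("utils", "", as.character(getRversion())))),
    .builtin_record("data_splitter",
      "Stratified train/test partitioning of a labelled table", dp,
      "labeled_table", "split_data"),
    .builtin_record("table_qc",
      "Drop incomplete rows and zero-variance features", dp,
      "labeled_table", "labeled_table"),
    .builtin_record("counts_qc",
      "Remove low-depth cells and rarely detected genes", dp,
      "count_matrix", "qc_count_matrix"),
    .builtin_record("counts_normalizer",
      "Median-depth scaling and log transform of counts", dp,
      "qc_count_matrix", "normalized_matrix"),
    .builtin_record("pca_embedder",
      "Principal-component embedding of a normalised matrix",
      "unsupervised embedding", "normalized_matrix", "embedding"),
    .builtin_record("kmeans_cluster",
      "k-means clustering of embedded cells",
      "unsupervised clustering", "embedding", "cluster_labels"),
    .builtin_record("classifier_pipeline",
      "Regularised logistic classification with importance scores",
      "supervised classification", "split_data", "classification_model",
      deps = list(dependency("glmnet", "https://cran.r-project.org", "4.1"))),
    .builtin_record("rfecv_optimizer",
      "Recursive feature elimination scored by cross-validation",
      "optimization", "classification_model", "optimized_model",
      deps = list(dependency("glmnet", "https://cran.r-project.org", "4.1"))))
  stats::setNames(recs, vapply(recs, function(r) r$name, ""))
}

#' Registration records of the single-cell scenario extras
#' @return Named list of four registration records.
#' @export
scenario_service_records <- function() {
  recs <- list(
    .builtin_record("counts_loader",
      "Load a cells-by-genes count CSV into an annotated matrix",
      "data processing", "counts_csv_path", "count_matrix"),
    .builtin_record("tsne_embedder",
      "t-SNE embedding (optional plug-in backend)",
      "unsupervised embedding", "normalized_matrix", "embedding",
      deps = list(dependency("Rtsne", "https://cran.r-project.org", ""))),
    .builtin_record("umap_embedder",
      "UMAP embedding (optional plug-in backend)",
      "unsupervised embedding", "normalized_matrix", "embedding",
      deps = list(dependency("uwot", "https://cran.r-project.org", ""))),
    .builtin_record("louvain_cluster",
      "Greedy modularity clustering on a k-nearest-neighbour graph",
      "unsupervised clustering", "embedding", "cluster_labels",
      deps = list(dependency("igraph", "https://cran.r-project.org", "2.1"))))
  stats::setNames(recs, vapply(recs, function(r) r$name, ""))
}

# Record for the on-demand feature-projection stage (registered lazily when
# a world-knowledge feature fact is reused).
.projector_record <- function() {
  .builtin_record("feature_projector",
    "Refit the classifier on a feature subset recorded in world knowledge",
    "optimization", "classification_model", "optimized_model")
}

#' Knowledge space initialised with the default services
#' @return A knowledge space whose \code{services} partition holds the nine
#'   default descriptors.
#' @export
default_registry <- function() {
  space <- knowledge_space()
  for (rec in default_service_records()) {
    space <- register_service(space, rec)$space
  }
  space
}

#' Knowledge space for the single-cell clustering scenario
#' @return [default_registry()] plus the four scenario extras.
#' @export
scenario_registry <- function() {
  space <- default_registry()
  for (rec in scenario_service_records()) {
    space <- register_service(space, rec)$space
  }
  space
}
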