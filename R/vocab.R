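#' Controlled vocabulary of data kinds
#'
#' Every service port is typed with one of these kinds; the planner composes
#' chains by matching the output kind of one service to the input kind of the
#' next. The vocabulary is frozen here: adding a kind is a code change, not
#' runtime data, so planner soundness can be checked statically.
#'
#' @return Character vector of valid data kinds.
#' @export
data_kinds <- function() {
  c(
    "csv_path", "labeled_table", "split_data", "classification_model",
    "optimized_model", "counts_csv_path", "count_matrix", "qc_count_matrix",
    "normalized_matrix", "embedding", "cluster_labels",
    "text_prompt", "text_answer", "image", "image_label"
  )
}

is_data_kind <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && x %in% data_kinds()
}

#' Project namespace prefix for knowledge-graph identifiers
#'
#' All identifiers minted by the framework live under a single namespace so
#' serialisations are stable and round trips deterministic.
#'
#' @return Single string, the IRI namespace.
#' @export
sf_namespace <- function() "http://semflow.org/kb#"

# Partition names of the knowledge space, in canonical order.
PARTITIONS <- c("services", "contexts", "policies", "world")
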