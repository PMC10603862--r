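#' @title Task contexts
#'
#' @description A task context is the semantic key of a task: the kind of
#' input data, a free-text application domain, the desired output kind, and
#' a dataset signature (row/column counts, ordered column names, modality).
#' All recorded knowledge — policies, world facts — is keyed by context, and
#' reuse decisions hinge on how two contexts compare: \code{EXACT} (same
#' task on the same data schema), \code{TRANSFERABLE} (same task, different
#' dataset — a recorded workflow can be retrained), or \code{NONE}.
#'
#' @name task_context
NULL

MATCH_LEVELS <- c(NONE = 0L, TRANSFERABLE = 1L, EXACT = 2L)

#' Build a dataset signature from a data preview
#'
#' Modality is inferred with a heuristic: an all-integer, non-negative
#' numeric table with at least 50 columns is treated as a count matrix,
#' anything else as tabular. The caller can override via \code{modality}.
#'
#' @param preview Data frame or matrix (the payload, or its head).
#' @param modality Optional override: one of \code{tabular}, \code{counts},
#'   \code{text}, \code{image}.
#' @return List with \code{n_rows}, \code{n_columns}, \code{column_names},
#'   \code{modality}.
#' @export
dataset_signature <- function(preview, modality = NULL) {
  if (is.null(dim(preview)) || nrow(preview) == 0L || ncol(preview) == 0L) {
    stop("empty dataset", call. = FALSE)
  }
  cn <- colnames(preview)
  if (is.null(cn)) cn <- paste0("V", seq_len(ncol(preview)))
  if (is.null(modality)) {
    vals <- if (is.data.frame(preview)) {
      if (all(vapply(preview, is.numeric, TRUE))) unlist(preview) else NA
    } else if (is.numeric(preview)) as.vector(preview) else NA
    counts_like <- !anyNA(vals[1]) && is.numeric(vals) &&
      all(vals >= 0 & vals == round(vals)) && ncol(preview) >= 50L
    modality <- if (isTRUE(counts_like)) "counts" else "tabular"
  }
  stopifnot(modality %in% c("tabular", "counts", "text", "image"))
  list(n_rows = as.numeric(nrow(preview)), n_columns = length(cn),
       column_names = as.character(cn), modality = modality)
}

#' Build a task context from a request and a data preview
#'
#' @param input_kind Data kind of the payload (see [data_kinds()]).
#' @param domain Free-text application domain (e.g. "medical").
#' @param desired_output_kind Data kind the task must produce; must differ
#'   from \code{input_kind} (a task requiring no computation is rejected).
#' @param data_preview Data frame or matrix used to derive the signature.
#' @param modality Optional modality override for the signature.
#' @return Object of class \code{task_context}.
#' @export
build_context <- function(input_kind, domain, desired_output_kind,
                          data_preview, modality = NULL) {
  stopifnot(is_data_kind(input_kind), is_data_kind(desired_output_kind),
            is.character(domain), length(domain) == 1L, nzchar(domain))
  if (identical(input_kind, desired_output_kind)) {
    stop("input kind equals desired output kind; nothing to compute",
         call. = FALSE)
  }
  sig <- dataset_signature(data_preview, modality)
  structure(list(input_kind = input_kind, domain = domain,
                 desired_output_kind = desired_output_kind, signature = sig),
            class = "task_context")
}

.sig_equal <- function(a, b) {
  # row count is ignored: two draws from the same schema should match
  identical(a$modality, b$modality) &&
    identical(a$column_names, b$column_names)
}

#' Compare two task contexts
#'
#' @param a,b \code{task_context} objects.
#' @return \code{"EXACT"} if input kind, domain (case-insensitive), desired
#'   output kind and signature all agree; \code{"TRANSFERABLE"} if only the
#'   signature differs; \code{"NONE"} otherwise. Symmetric.
#' @export
match_contexts <- function(a, b) {
  stopifnot(inherits(a, "task_context"), inherits(b, "task_context"))
  core <- identical(a$input_kind, b$input_kind) &&
    identical(a$desired_output_kind, b$desired_output_kind) &&
    identical(tolower(a$domain), tolower(b$domain))
  if (!core) return("NONE")
  if (.sig_equal(a$signature, b$signature)) "EXACT" else "TRANSFERABLE"
}

# Deterministic identifier for a context: md5 of its canonical JSON form.
context_id <- function(ctx) {
  canon <- jsonlite::toJSON(list(
    i = ctx$input_kind, d = ctx$domain, o = ctx$desired_output_kind,
    r = ctx$signature$n_rows, c = ctx$signature$column_names,
    m = ctx$signature$modality), auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(as.character(canon), tf, eos = NULL)
  paste0("context/", unname(tools::md5sum(tf)))
}

#' Convert a context to triples
#'
#' Lossless: [context_from_triples()] on the result reconstructs an equal
#' context, column names preserved in order.
#'
#' @param ctx A \code{task_context}.
#' @return Data frame of triples for the \code{contexts} partition.
#' @export
context_to_statements <- function(ctx) {
  id <- context_id(ctx)
  cols <- as.character(jsonlite::toJSON(ctx$signature$column_names))
  do.call(rbind, list(
    triple(id, "a", "TaskContext"),
    triple(id, "hasInputKind", lit(ctx$input_kind)),
    triple(id, "hasDomain", lit(ctx$domain)),
    triple(id, "hasOutputKind", lit(ctx$desired_output_kind)),
    triple(id, "hasRows", lit(as.numeric(ctx$signature$n_rows))),
    triple(id, "hasColumnNames", lit(cols)),
    triple(id, "hasModality", lit(ctx$signature$modality))))
}

#' Reconstruct a context stored under an identifier
#' @param space A knowledge space.
#' @param id Context identifier (subject of its triples).
#' @export
context_from_triples <- function(space, id) {
  df <- space$partitions$contexts
  field <- function(pred) .node_field(df, id, pred)
  cols <- jsonlite::fromJSON(field("hasColumnNames"))
  if (length(cols) == 0L) cols <- character(0)
  structure(list(
    input_kind = field("hasInputKind"), domain = field("hasDomain"),
    desired_output_kind = field("hasOutputKind"),
    signature = list(n_rows = as.numeric(field("hasRows")),
                     n_columns = length(cols),
                     column_names = as.character(cols),
                     modality = field("hasModality"))),
    class = "task_context")
}

# All context identifiers recorded in the space.
context_ids <- function(space) {
  df <- space$partitions$contexts
  sort(unique(df$s[df$p == "a" & df$o == "TaskContext"]))
}

#' @export
print.task_context <- function(x, ...) {
  cat(sprintf("<task_context> %s -> %s | domain: %s | %d x %d %s\n",
              x$input_kind, x$desired_output_kind, x$domain,
              x$signature$n_rows, x$signature$n_columns,
              x$signature$modality))
  invisible(x)
}
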