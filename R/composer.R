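#' @title Workflow composition
#'
#' @description The reasoning step. A workflow is an ordered chain of
#' registered services in which the output data kind of each step equals the
#' input data kind of the next, the first step consumes the task's input
#' kind and the last produces the desired output kind. The planner first
#' checks whether a single service solves the task; otherwise it enumerates
#' every simple chain (no repeated service) up to a depth bound by
#' depth-first search over the digraph whose nodes are data kinds and whose
#' edges are services. Candidates are ranked by length, then by cumulative
#' recorded reward of their services, then lexicographically — a total,
#' deterministic order.
#'
#' @name composer
NULL

# package-level counters (planner invocations are observable so tests and
# reports can verify that transfer/exact reuse skips planning)
.sf_state <- new.env(parent = emptyenv())
.sf_state$planner_calls <- 0L

#' Number of planner invocations since the last reset
#' @export
planner_call_count <- function() .sf_state$planner_calls

#' @rdname planner_call_count
#' @export
reset_planner_calls <- function() {
  .sf_state$planner_calls <- 0L
  invisible(NULL)
}

#' Construct a workflow
#'
#' Zero steps are permitted only so that planning failures can be recorded
#' as policies with an empty succeeded list; the planner never emits one.
#' @param steps Character vector of service names, in execution order.
#' @export
workflow <- function(steps) {
  stopifnot(is.character(steps), !anyDuplicated(steps))
  structure(list(steps = steps), class = "workflow")
}

#' Check a workflow against a context and registry
#'
#' Verifies every chain invariant: all steps registered and distinct, first
#' input kind equals the context's input kind, last output kind equals the
#' desired output kind, and each adjacent pair I/O-compatible.
#'
#' @param wf A [workflow()].
#' @param ctx A \code{task_context}.
#' @param space Knowledge space holding the registry.
#' @return \code{TRUE}, or a character vector of violation messages.
#' @export
validate_workflow <- function(wf, ctx, space) {
  probs <- character(0)
  nm <- registry_names(space)
  if (anyDuplicated(wf$steps)) probs <- c(probs, "repeated service")
  unknown <- setdiff(wf$steps, nm)
  if (length(unknown)) {
    return(c(probs, paste("unregistered service:",
                          paste(unknown, collapse = ", "))))
  }
  ds <- lapply(wf$steps, descriptor_from_triples, space = space)
  if (service_input_kind(ds[[1]]) != ctx$input_kind) {
    probs <- c(probs, "first step does not accept the task input kind")
  }
  if (service_output_kind(ds[[length(ds)]]) != ctx$desired_output_kind) {
    probs <- c(probs, "last step does not produce the desired output kind")
  }
  if (length(ds) > 1L) {
    for (i in seq_len(length(ds) - 1L)) {
      if (service_output_kind(ds[[i]]) != service_input_kind(ds[[i + 1]])) {
        probs <- c(probs, sprintf("steps %d -> %d not I/O compatible", i, i + 1L))
      }
    }
  }
  if (length(probs)) probs else TRUE
}

#' Find a single service solving the task outright
#'
#' @param ctx A \code{task_context}.
#' @param space Knowledge space holding the registry.
#' @return List of matching descriptors (usually length 0 or 1; several are
#'   all returned so ranking can choose).
#' @export
find_single_service <- function(ctx, space) {
  find_services(space, input_kind = ctx$input_kind,
                output_kind = ctx$desired_output_kind)
}

#' Enumerate all I/O-compatible workflows for a task
#'
#' Depth-first enumeration of simple chains from the context's input kind to
#' its desired output kind. Single-service solutions are included (they rank
#' ahead of longer chains by the length-first sort).
#'
#' @param ctx A \code{task_context}.
#' @param space Knowledge space holding the registry.
#' @param max_depth Maximum chain length (default 8).
#' @return List of [workflow()]s ordered by (length, lexicographic steps).
#'   Empty list when no chain exists.
#' @export
compose <- function(ctx, space, max_depth = 8L) {
  stopifnot(max_depth >= 1L)
  .sf_state$planner_calls <- .sf_state$planner_calls + 1L
  ds <- registry_descriptors(space)   # sorted by name
  ins <- vapply(ds, service_input_kind, "")
  outs <- vapply(ds, service_output_kind, "")
  nms <- names(ds)
  found <- list()
  dfs <- function(kind, path) {
    if (length(path) > 0L && kind == ctx$desired_output_kind) {
      # record, but keep extending: a chain may pass through the goal kind
      # and reach it again via other services
      found[[length(found) + 1L]] <<- workflow(path)
    }
    if (length(path) >= max_depth) return()
    for (i in seq_along(nms)) {
      if (ins[[i]] == kind && !(nms[[i]] %in% path)) {
        dfs(outs[[i]], c(path, nms[[i]]))
      }
    }
  }
  dfs(ctx$input_kind, character(0))
  if (!length(found)) return(list())
  len <- vapply(found, function(w) length(w$steps), 0L)
  key <- vapply(found, function(w) paste(w$steps, collapse = "\r"), "")
  found[order(len, key, method = "radix")]
}

#' Rank candidate workflows using policy knowledge
#'
#' Sort key: chain length ascending, cumulative recorded service reward
#' descending, lexicographic step-name tuple ascending. Total and stable, so
#' ranking is idempotent.
#'
#' @param candidates List of [workflow()]s.
#' @param space Knowledge space (its \code{policies} partition supplies the
#'   rewards; an empty store gives a pure length/lexicographic order).
#' @return The candidates, re-ordered.
#' @export
rank_workflows <- function(candidates, space) {
  if (!length(candidates)) return(candidates)
  len <- vapply(candidates, function(w) length(w$steps), 0L)
  rew <- vapply(candidates, function(w)
    sum(vapply(w$steps, service_priority, 0, space = space)), 0)
  key <- vapply(candidates, function(w) paste(w$steps, collapse = "\r"), "")
  candidates[order(len, -rew, key, method = "radix")]
}

#' Filter candidates by user stage preferences
#'
#' A preference pins one pipeline stage — identified by the data kind that
#' stage produces — to a named service. Only candidates that contain a step
#' producing that kind, and whose step is the preferred service, survive.
#'
#' @param candidates List of [workflow()]s.
#' @param prefs Named list/character vector: names are stage output kinds,
#'   values preferred service names.
#' @param space Knowledge space holding the registry (preferences must name
#'   registered services).
#' @return The filtered candidate list (order preserved).
#' @export
apply_preferences <- function(candidates, prefs, space) {
  if (is.null(prefs) || !length(prefs)) return(candidates)
  prefs <- as.list(prefs)
  nm <- registry_names(space)
  for (svc in unlist(prefs)) {
    if (!svc %in% nm) {
      stop("preference names unregistered service: ", svc, call. = FALSE)
    }
  }
  out_kind <- function(s) service_output_kind(descriptor_from_triples(space, s))
  keep <- vapply(candidates, function(w) {
    kinds <- vapply(w$steps, out_kind, "")
    all(vapply(names(prefs), function(stage) {
      at <- which(kinds == stage)
      length(at) > 0L && all(w$steps[at] == prefs[[stage]])
    }, TRUE))
  }, TRUE)
  candidates[keep]
}

#' @export
print.workflow <- function(x, ...) {
  cat("<workflow>", paste(x$steps, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
format.workflow <- function(x, ...) paste(x$steps, collapse = " -> ")
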