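#' @title Workflow execution
#'
#' @description Runs a workflow step by step on a payload. Each step's
#' descriptor names an invoke path; local paths resolve to in-process
#' callables registered at load time, remote URIs are stored but refused at
#' execution. Execution never throws for a failing step: it returns a trace
#' recording exactly how far the run got — statuses before the failure are
#' \code{succeeded}, the failing step \code{failed}, everything after
#' \code{skipped}. A single seed is threaded to every stochastic service so
#' replays are reproducible.
#'
#' @name executor
NULL

.sf_callables <- new.env(parent = emptyenv())

#' Register an in-process callable for an invoke path
#'
#' @param invoke_path The invoke path as it appears in a descriptor.
#' @param fn Function of \code{(value, params, seed)} returning the step's
#'   output value.
#' @export
register_callable <- function(invoke_path, fn) {
  stopifnot(is.character(invoke_path), length(invoke_path) == 1L,
            is.function(fn))
  assign(invoke_path, fn, envir = .sf_callables)
  invisible(invoke_path)
}

.resolve_callable <- function(invoke_path) {
  if (grepl("^[a-z][a-z0-9+.-]*://", invoke_path)) {
    stop("remote invoke path refused (local execution only): ", invoke_path,
         call. = FALSE)
  }
  if (!exists(invoke_path, envir = .sf_callables, inherits = FALSE)) {
    stop("no callable registered for invoke path: ", invoke_path,
         call. = FALSE)
  }
  get(invoke_path, envir = .sf_callables, inherits = FALSE)
}

#' Wrap a value with its data kind
#' @param kind A data kind (see [data_kinds()]).
#' @param value The raw value.
#' @export
sf_payload <- function(kind, value) {
  stopifnot(is_data_kind(kind))
  structure(list(kind = kind, value = value), class = "sf_payload")
}

#' Execute a workflow on a payload
#'
#' @param wf A [workflow()].
#' @param payload An [sf_payload()] whose kind matches the first step's
#'   input port.
#' @param space Knowledge space holding the registry.
#' @param seed Integer seed threaded to every step.
#' @param params Named list of per-service parameter lists, keyed by service
#'   name (e.g. \code{list(cluster_kmeans = list(k = 3))}).
#' @return An object of class \code{execution_trace}.
#' @export
execute_workflow <- function(wf, payload, space, seed = 1L, params = list()) {
  stopifnot(inherits(wf, "workflow"), inherits(payload, "sf_payload"))
  ds <- lapply(wf$steps, descriptor_from_triples, space = space)
  n <- length(ds)
  status <- rep("skipped", n)
  failure_index <- NA_integer_
  err <- NULL
  metrics <- list()
  value <- payload$value
  if (payload$kind != service_input_kind(ds[[1]])) {
    status[1] <- "failed"; failure_index <- 1L
    err <- sprintf("payload kind '%s' does not match first step input '%s'",
                   payload$kind, service_input_kind(ds[[1]]))
  } else {
    for (i in seq_len(n)) {
      d <- ds[[i]]
      p <- params[[d$name]] %||% list()
      res <- tryCatch(
        .resolve_callable(d$invoke_path)(value, p, seed),
        error = function(e) e)
      if (inherits(res, "error")) {
        status[i] <- "failed"; failure_index <- i
        err <- conditionMessage(res)
        break
      }
      status[i] <- "succeeded"
      sm <- attr(res, "sf_metrics")
      if (!is.null(sm)) metrics[names(sm)] <- sm
      value <- res
    }
  }
  final <- if (is.na(failure_index)) {
    sf_payload(service_output_kind(ds[[n]]), value)
  } else NULL
  structure(list(workflow = wf, step_status = status,
                 failure_index = failure_index, final_output = final,
                 metrics = metrics, error = err, seed = seed,
                 feature_reuse = "feature_projector" %in% wf$steps),
            class = "execution_trace")
}

#' Evaluate an execution trace against its task context
#'
#' Success (\code{state = 1}) means every step completed and the final
#' output kind equals the context's desired output kind; the final artifact
#' is then persisted under a content-addressed directory together with a
#' JSON workflow manifest, and its location returned. Failure registers no
#' solution.
#'
#' @param trace An \code{execution_trace}.
#' @param ctx The \code{task_context} of the run.
#' @param solution_store Directory for persisted solutions (created if
#'   needed). Defaults to option \code{semflow.solution_store}, falling back
#'   to a per-session temporary directory.
#' @return List with \code{state} (1 or 0), \code{solution_iloc} (path or
#'   \code{NULL}) and \code{metric} (number or \code{NULL}).
#' @export
evaluate_outcome <- function(trace, ctx, solution_store = NULL) {
  stopifnot(inherits(trace, "execution_trace"))
  metric <- trace$metrics$accuracy %||% trace$metrics$score %||% NULL
  ok <- is.na(trace$failure_index) && !is.null(trace$final_output) &&
    trace$final_output$kind == ctx$desired_output_kind
  if (!ok) return(list(state = 0L, solution_iloc = NULL, metric = metric))
  store <- solution_store %||%
    getOption("semflow.solution_store",
              file.path(tempdir(), "semflow_solutions"))
  manifest <- list(steps = trace$workflow$steps,
                   output_kind = trace$final_output$kind,
                   seed = trace$seed,
                   metrics = trace$metrics,
                   context = list(input_kind = ctx$input_kind,
                                  domain = ctx$domain,
                                  desired_output_kind = ctx$desired_output_kind,
                                  columns = ctx$signature$column_names))
  mj <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(); writeChar(as.character(mj), tf, eos = NULL)
  hash <- unname(tools::md5sum(tf)); unlink(tf)
  iloc <- file.path(store, hash)
  dir.create(iloc, recursive = TRUE, showWarnings = FALSE)
  writeLines(as.character(mj), file.path(iloc, "manifest.json"))
  saveRDS(trace$final_output, file.path(iloc, "artifact.rds"))
  list(state = 1L, solution_iloc = iloc, metric = metric)
}

#' Reload a persisted solution and apply it to new data
#'
#' @param iloc Solution directory written by [evaluate_outcome()].
#' @param data Optional new data (a data frame) to which a persisted model
#'   is applied; model payloads expose a \code{predict} closure.
#' @return List with the \code{manifest}, the reloaded \code{artifact}, and
#'   \code{predictions} when \code{data} was supplied and the artifact is a
#'   model.
#' @export
replay_solution <- function(iloc, data = NULL) {
  mf <- file.path(iloc, "manifest.json")
  af <- file.path(iloc, "artifact.rds")
  if (!file.exists(mf) || !file.exists(af)) {
    stop("no persisted solution at: ", iloc, call. = FALSE)
  }
  manifest <- jsonlite::fromJSON(mf)
  artifact <- readRDS(af)
  preds <- NULL
  if (!is.null(data) && is.list(artifact$value) &&
      is.function(artifact$value$predict)) {
    preds <- artifact$value$predict(data)
  }
  list(manifest = manifest, artifact = artifact, predictions = preds)
}

#' @export
print.execution_trace <- function(x, ...) {
  cat("<execution_trace>", format(x$workflow), "\n")
  cat("  status:", paste(x$step_status, collapse = ", "), "\n")
  if (!is.na(x$failure_index)) {
    cat("  failed at step", x$failure_index, ":", x$error, "\n")
  }
  if (length(x$metrics)) {
    cat("  metrics:", paste(names(x$metrics), unlist(x$metrics),
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
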