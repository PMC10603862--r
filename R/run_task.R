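#' @title Task orchestration
#'
#' @description [run_task()] is the request layer: it builds the task
#' context, consults the policy store, and takes the cheapest adequate
#' route — load a recorded solution on an \code{EXACT} match, retrain a
#' recorded workflow on a \code{TRANSFERABLE} match, or invoke the planner,
#' execute the ranked candidates, and record every outcome as policy
#' knowledge. Feature-selection facts in world knowledge short-circuit the
#' optimisation stage when the dataset schema matches exactly.
#'
#' @name run_task
NULL

#' Runtime configuration
#'
#' @param seed Default seed threaded through planning and execution.
#' @param max_depth Planner chain-length bound.
#' @param qc_percentile Count-QC depth percentile.
#' @param cv_folds Folds for the RFE-CV optimiser.
#' @param top_k Execute at most this many ranked candidates (default all).
#' @param knowledge_store Path for persisted knowledge (N-Triples or
#'   Turtle, by extension).
#' @param solution_store Directory for persisted solutions.
#' @param verbose Emit layer-tagged progress messages.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, max_depth = 8L, qc_percentile = 5,
                       cv_folds = 5L, top_k = Inf,
                       knowledge_store = NULL, solution_store = NULL,
                       verbose = FALSE) {
  stopifnot(max_depth >= 1L, qc_percentile > 0, qc_percentile < 100,
            cv_folds >= 2L, top_k >= 1)
  structure(list(seed = as.integer(seed), max_depth = as.integer(max_depth),
                 qc_percentile = qc_percentile,
                 cv_folds = as.integer(cv_folds), top_k = top_k,
                 knowledge_store = knowledge_store,
                 solution_store = solution_store, verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Load a runtime configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#' @param path YAML file.
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

.log <- function(config, layer, ...) {
  if (isTRUE(config$verbose)) message(sprintf("[%s] ", layer), ...)
}

#' Save / load a knowledge space to disk
#'
#' Dialect chosen by extension: \code{.ttl} gives Turtle, anything else
#' N-Triples.
#' @param space A knowledge space.
#' @param path File path.
#' @export
ks_save <- function(space, path) {
  dialect <- if (grepl("\\.ttl$", path)) "turtle" else "ntriples"
  writeLines(ks_serialize(space, dialect), path, sep = "")
  invisible(path)
}

#' @rdname ks_save
#' @export
ks_load <- function(path) {
  dialect <- if (grepl("\\.ttl$", path)) "turtle" else "ntriples"
  ks_parse(paste(readLines(path), collapse = "\n"), dialect)
}

# Record a planning failure: state 0, empty workflow, no rewards.
record_planning_failure <- function(space, ctx) {
  trace <- structure(list(workflow = workflow(character(0)),
                          step_status = character(0),
                          failure_index = 0L, final_output = NULL,
                          metrics = list(), error = "no admissible workflow",
                          seed = NA_integer_, feature_reuse = FALSE),
                     class = "execution_trace")
  record_outcome(space, ctx, trace, list(state = 0L, solution_iloc = NULL,
                                         metric = NULL))
}

# Swap the optimisation stage for a projection stage using a stored feature
# subset; registers the projector service on first use.
.substitute_feature_reuse <- function(candidates, space, features) {
  if (!"feature_projector" %in% registry_names(space)) {
    space <- register_service(space, .projector_record())$space
  }
  candidates <- lapply(candidates, function(w) {
    if ("rfecv_optimizer" %in% w$steps) {
      w$steps[w$steps == "rfecv_optimizer"] <- "feature_projector"
      workflow(w$steps)
    } else w
  })
  # substitution can collapse two candidates onto the same chain
  key <- vapply(candidates, function(w) paste(w$steps, collapse = "\r"), "")
  list(space = space, candidates = candidates[!duplicated(key)])
}

#' Plan, execute and learn from one task
#'
#' @param input_kind Data kind of the payload.
#' @param domain Free-text application domain.
#' @param desired_output_kind Data kind the task must produce.
#' @param data The payload: a path for \code{csv_path} /
#'   \code{counts_csv_path} input kinds, otherwise the in-memory value.
#' @param space Knowledge space (registry plus accumulated knowledge).
#' @param config A [run_config()].
#' @param prefs Stage preferences for [apply_preferences()].
#' @param params Per-service parameter overrides (see
#'   [execute_workflow()]).
#' @param dry_run Plan and rank only; execute nothing, record nothing.
#' @return List with \code{report} (class \code{sf_report}) and the updated
#'   \code{space}. The report records the route taken (\code{exact},
#'   \code{transfer}, \code{plan} or \code{failure}), whether the planner
#'   was invoked, the ranked candidates, per-candidate outcomes, the chosen
#'   solution and whether a stored feature subset was reused.
#' @export
run_task <- function(input_kind, domain, desired_output_kind, data,
                     space, config = run_config(), prefs = NULL,
                     params = list(), dry_run = FALSE) {
  stopifnot(inherits(config, "run_config"))
  preview <- data
  if (input_kind %in% c("csv_path", "counts_csv_path")) {
    if (!is.character(data) || !file.exists(data)) {
      stop("data path not found: ", data, call. = FALSE)
    }
    preview <- if (input_kind == "csv_path") {
      utils::read.csv(data, check.names = FALSE)
    } else {
      utils::read.csv(data, row.names = 1, check.names = FALSE)
    }
  }
  modality <- if (input_kind == "counts_csv_path") "counts" else NULL
  ctx <- build_context(input_kind, domain, desired_output_kind, preview,
                       modality = modality)
  .log(config, "request", "task ", input_kind, " -> ", desired_output_kind,
       " in domain '", domain, "'")
  payload <- sf_payload(input_kind, data)

  # merge config-driven defaults under user-supplied params
  defaults <- list(counts_qc = list(depth_percentile = config$qc_percentile),
                   rfecv_optimizer = list(folds = config$cv_folds))
  for (nm in names(defaults)) {
    params[[nm]] <- utils::modifyList(defaults[[nm]], params[[nm]] %||% list())
  }

  report <- list(context = ctx, route = NULL, planner_invoked = FALSE,
                 candidates = list(), executed = list(), chosen = NULL,
                 feature_reuse = FALSE, knowledge_written = 0L)
  size0 <- ks_size(space)

  hits <- lookup_policy(space, ctx)
  exact <- Filter(function(h) h$level == "EXACT" && h$record$state == 1L, hits)
  transferable <- Filter(function(h)
    h$level == "TRANSFERABLE" && h$record$state == 1L, hits)

  if (!dry_run && length(exact)) {
    .log(config, "knowledge", "exact policy hit; loading recorded solution")
    rec <- exact[[1]]$record
    report$route <- "exact"
    report$chosen <- list(workflow = rec$workflow, metric = rec$metric,
                          solution_iloc = rec$solution_iloc,
                          policy = rec$id)
    report$knowledge_written <- ks_size(space) - size0
    class(report) <- "sf_report"
    return(list(report = report, space = space))
  }

  if (!dry_run && length(transferable)) {
    .log(config, "knowledge", "transferable policy hit; retraining recorded ",
         "workflow")
    tr <- transfer_solution(space, ctx, payload, seed = config$seed,
                            params = params,
                            solution_store = config$solution_store)
    space <- tr$space
    report$route <- "transfer"
    report$candidates <- list(tr$source$workflow)
    report$executed <- list(list(workflow = tr$trace$workflow,
                                 state = tr$outcome$state,
                                 metric = tr$outcome$metric,
                                 solution_iloc = tr$outcome$solution_iloc,
                                 policy = tr$record$id))
    if (tr$outcome$state == 1L) report$chosen <- report$executed[[1]]
    report$knowledge_written <- ks_size(space) - size0
    class(report) <- "sf_report"
    return(list(report = report, space = space))
  }

  .log(config, "reasoning", "no reusable policy; composing candidates")
  candidates <- compose(ctx, space, max_depth = config$max_depth)
  report$planner_invoked <- TRUE
  candidates <- apply_preferences(candidates, prefs, space)

  stored <- reuse_features(space, ctx$signature)
  if (!is.null(stored) &&
      any(vapply(candidates, function(w) "rfecv_optimizer" %in% w$steps, TRUE))) {
    .log(config, "knowledge", "feature fact matches schema; projecting to ",
         length(stored), " stored features")
    sub <- .substitute_feature_reuse(candidates, space, stored)
    space <- sub$space
    candidates <- sub$candidates
    params$feature_projector <-
      utils::modifyList(list(features = stored),
                        params$feature_projector %||% list())
    report$feature_reuse <- TRUE
  }

  candidates <- rank_workflows(candidates, space)
  report$candidates <- candidates

  if (!length(candidates)) {
    .log(config, "reasoning", "planning failed; recording failure policy")
    report$route <- "failure"
    if (!dry_run) {
      rec <- record_planning_failure(space, ctx)
      space <- rec$space
      report$executed <- list(list(workflow = rec$record$workflow,
                                   state = 0L, metric = NULL,
                                   solution_iloc = NULL,
                                   policy = rec$record$id))
    }
    report$knowledge_written <- ks_size(space) - size0
    class(report) <- "sf_report"
    return(list(report = report, space = space))
  }

  report$route <- "plan"
  if (dry_run) {
    class(report) <- "sf_report"
    return(list(report = report, space = space))
  }

  n_exec <- min(length(candidates), config$top_k)
  for (i in seq_len(n_exec)) {
    wf <- candidates[[i]]
    .log(config, "reasoning", "executing candidate ", i, ": ", format(wf))
    trace <- execute_workflow(wf, payload, space, seed = config$seed,
                              params = params)
    outcome <- evaluate_outcome(trace, ctx, config$solution_store)
    rec <- record_outcome(space, ctx, trace, outcome)
    space <- rec$space
    report$executed[[i]] <- list(workflow = wf, state = outcome$state,
                                 metric = outcome$metric,
                                 solution_iloc = outcome$solution_iloc,
                                 policy = rec$record$id,
                                 feature_reuse = trace$feature_reuse)
    # a successful optimisation yields a reusable feature fact
    if (outcome$state == 1L && !trace$feature_reuse &&
        "rfecv_optimizer" %in% wf$steps &&
        !is.null(trace$final_output$value$selected_features)) {
      fact <- feature_fact(ctx$signature$column_names,
                           trace$final_output$value$selected_features,
                           source_policy = rec$record$id,
                           metric = outcome$metric %||% NA_real_)
      space <- record_feature_fact(space, fact)
    }
  }
  succ <- Filter(function(e) e$state == 1L, report$executed)
  if (length(succ)) {
    met <- vapply(succ, function(e) e$metric %||% -Inf, 0)
    report$chosen <- succ[[which.max(met)]]
  }
  report$knowledge_written <- ks_size(space) - size0
  class(report) <- "sf_report"
  list(report = report, space = space)
}

#' @export
print.sf_report <- function(x, ...) {
  cat("<task report> route:", x$route,
      "| planner invoked:", x$planner_invoked, "\n")
  if (length(x$candidates)) {
    cat("  candidates (", length(x$candidates), "):\n", sep = "")
    for (w in x$candidates) cat("    ", format(w), "\n")
  }
  for (e in x$executed) {
    cat(sprintf("  run: %s  state=%d%s\n", format(e$workflow), e$state,
                if (!is.null(e$metric))
                  sprintf("  metric=%.3f", e$metric) else ""))
  }
  if (!is.null(x$chosen)) {
    cat("  chosen:", format(x$chosen$workflow))
    if (!is.null(x$chosen$metric)) cat(sprintf("  (metric %.3f)", x$chosen$metric))
    cat("\n")
  }
  if (x$feature_reuse) cat("  feature subset reused from world knowledge\n")
  cat("  knowledge triples written:", x$knowledge_written, "\n")
  invisible(x)
}

#' Tabular dumps of recorded knowledge
#'
#' @param space A knowledge space.
#' @return \code{knowledge_policies}: one row per policy record;
#'   \code{knowledge_contexts}: one row per stored context;
#'   \code{knowledge_world}: one row per world fact.
#' @export
knowledge_policies <- function(space) {
  ids <- policy_ids(space)
  do.call(rbind, lapply(ids, function(id) {
    r <- policy_from_triples(space, id)
    data.frame(id = r$id, state = r$state,
               workflow = paste(r$workflow$steps, collapse = " -> "),
               solution_reward = r$solution_reward,
               metric = r$metric %||% NA_real_,
               solution_iloc = r$solution_iloc %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname knowledge_policies
#' @export
knowledge_contexts <- function(space) {
  ids <- context_ids(space)
  do.call(rbind, lapply(ids, function(id) {
    cx <- context_from_triples(space, id)
    data.frame(id = id, input_kind = cx$input_kind, domain = cx$domain,
               desired_output_kind = cx$desired_output_kind,
               n_rows = cx$signature$n_rows,
               n_columns = cx$signature$n_columns,
               modality = cx$signature$modality, stringsAsFactors = FALSE)
  }))
}

#' @rdname knowledge_policies
#' @export
knowledge_world <- function(space) {
  df <- space$partitions$world
  ids <- unique(df$s[df$p == "a"])
  do.call(rbind, lapply(ids, function(id) {
    type <- df$o[df$s == id & df$p == "a"][1]
    detail <- switch(type,
      FeatureSelectionFact = paste("selected:",
        paste(jsonlite::fromJSON(.node_field(df, id, "hasSelected")),
              collapse = ", ")),
      AnswerFact = paste("topic:", .node_field(df, id, "hasTopic")),
      ImageVectorFact = paste("label:", .node_field(df, id, "hasLabel")),
      "")
    data.frame(id = id, type = type, detail = detail,
               stringsAsFactors = FALSE)
  }))
}
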