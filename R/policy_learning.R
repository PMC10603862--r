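#' @title Policy knowledge and rewards
#'
#' @description The reinforcement-style layer. Every task outcome is
#' recorded as a policy: a link to the task context, a binary state (1 =
#' success, 0 = failure), the workflow, the persisted solution location on
#' success, and per-service rewards. A successful n-step workflow
#' distributes a total reward of 1 equally — each step earns exactly 1/n. A
#' failed run still rewards the m steps that completed, 1/m each, so a
#' service that works keeps accumulating credit and is preferred when
#' ranking future candidates. Rewards accumulate additively across records
#' with no decay.
#'
#' @name policy_learning
NULL

.policy_seq <- function(space) {
  df <- space$partitions$policies
  length(unique(df$s[df$p == "a" & df$o == "PolicyRecord"]))
}

#' Record the outcome of an executed workflow
#'
#' @param space A knowledge space.
#' @param ctx The task's \code{task_context} (stored in the \code{contexts}
#'   partition if not already present).
#' @param trace The \code{execution_trace} of the run.
#' @param outcome Result of [evaluate_outcome()] for that trace.
#' @return List with the updated \code{space} and the \code{record} (a
#'   \code{policy_record}).
#' @export
record_outcome <- function(space, ctx, trace, outcome) {
  stopifnot(inherits(ctx, "task_context"), inherits(trace, "execution_trace"))
  space <- ks_add_triples(space, "contexts", context_to_statements(ctx))
  k <- .policy_seq(space) + 1L
  id <- sprintf("policy/%06d", k)

  succeeded <- trace$workflow$steps[trace$step_status == "succeeded"]
  state <- as.integer(outcome$state)
  step_rewards <- if (state == 1L) {
    n <- length(trace$workflow$steps)
    stats::setNames(rep(1 / n, n), trace$workflow$steps)
  } else if (length(succeeded) >= 1L) {
    m <- length(succeeded)
    stats::setNames(rep(1 / m, m), succeeded)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  metric <- outcome$metric
  solution_reward <- if (state == 1L) {
    if (!is.null(metric)) min(max(metric, 0), 1) else 1
  } else 0

  tr <- list(
    triple(id, "a", "PolicyRecord"),
    triple(id, "hasContext", context_id(ctx)),
    triple(id, "hasState", lit(as.numeric(state))),
    triple(id, "hasSeq", lit(as.numeric(k))),
    triple(id, "hasWorkflow",
           lit(as.character(jsonlite::toJSON(trace$workflow$steps)))),
    triple(id, "hasSolutionReward", lit(solution_reward)))
  if (state == 1L && !is.null(outcome$solution_iloc)) {
    tr <- c(tr, list(triple(id, "hasSolutionIloc", lit(outcome$solution_iloc))))
  }
  if (!is.null(metric)) {
    tr <- c(tr, list(triple(id, "hasMetric", lit(as.numeric(metric)))))
  }
  for (i in seq_along(step_rewards)) {
    node <- paste0(id, "/reward/", i)
    tr <- c(tr, list(
      triple(id, "hasStepReward", node),
      triple(node, "index", lit(as.numeric(i))),
      triple(node, "forService", lit(names(step_rewards)[i])),
      triple(node, "rewardValue", lit(unname(step_rewards[i])))))
  }
  space <- ks_add_triples(space, "policies", do.call(rbind, tr))

  record <- structure(list(
    id = id, context_ref = context_id(ctx), state = state,
    solution_iloc = outcome$solution_iloc,
    workflow = trace$workflow, solution_reward = solution_reward,
    step_rewards = step_rewards, metric = metric, seq = k),
    class = "policy_record")
  list(space = space, record = record)
}

# All policy identifiers in the store, in sequence order.
policy_ids <- function(space) {
  df <- space$partitions$policies
  ids <- unique(df$s[df$p == "a" & df$o == "PolicyRecord"])
  if (!length(ids)) return(character(0))
  seqs <- vapply(ids, function(id)
    as.numeric(.node_field(df, id, "hasSeq")), 0)
  ids[order(seqs)]
}

#' Reconstruct one policy record
#' @param space A knowledge space.
#' @param id Policy identifier.
#' @export
policy_from_triples <- function(space, id) {
  df <- space$partitions$policies
  field <- function(pred) .node_field(df, id, pred)
  opt <- function(pred) {
    v <- df$o[df$s == id & df$p == pred]
    if (length(v)) v[[1]] else NULL
  }
  steps <- as.character(jsonlite::fromJSON(field("hasWorkflow")))
  nodes <- df$o[df$s == id & df$p == "hasStepReward"]
  step_rewards <- stats::setNames(numeric(0), character(0))
  if (length(nodes)) {
    idx <- vapply(nodes, function(nd) as.numeric(.node_field(df, nd, "index")), 0)
    nodes <- nodes[order(idx)]
    step_rewards <- stats::setNames(
      vapply(nodes, function(nd) as.numeric(.node_field(df, nd, "rewardValue")), 0),
      vapply(nodes, function(nd) .node_field(df, nd, "forService"), ""))
  }
  metric <- opt("hasMetric")
  structure(list(
    id = id, context_ref = field("hasContext"),
    state = as.integer(as.numeric(field("hasState"))),
    solution_iloc = opt("hasSolutionIloc"),
    workflow = workflow(steps),
    solution_reward = as.numeric(field("hasSolutionReward")),
    step_rewards = step_rewards,
    metric = if (is.null(metric)) NULL else as.numeric(metric),
    seq = as.numeric(field("hasSeq"))), class = "policy_record")
}

#' Search the policy store for records matching a context
#'
#' @param space A knowledge space.
#' @param ctx A \code{task_context}.
#' @return List of \code{list(record, level)} for every policy whose stored
#'   context matches at \code{EXACT} or \code{TRANSFERABLE} level, sorted by
#'   match level (EXACT first), then solution reward descending, then
#'   recency (most recent first).
#' @export
lookup_policy <- function(space, ctx) {
  ids <- policy_ids(space)
  out <- list()
  for (id in ids) {
    rec <- policy_from_triples(space, id)
    stored_ctx <- tryCatch(context_from_triples(space, rec$context_ref),
                           error = function(e) NULL)
    if (is.null(stored_ctx)) next
    level <- match_contexts(ctx, stored_ctx)
    if (level == "NONE") next
    out[[length(out) + 1L]] <- list(record = rec, level = level)
  }
  if (!length(out)) return(out)
  lv <- vapply(out, function(h) MATCH_LEVELS[[h$level]], 0L)
  rw <- vapply(out, function(h) h$record$solution_reward, 0)
  sq <- vapply(out, function(h) h$record$seq, 0)
  out[order(-lv, -rw, -sq)]
}

#' Cumulative recorded reward of one service
#'
#' Sum of the service's step rewards across every policy record; 0 when the
#' service was never rewarded.
#'
#' @param service_name Service name.
#' @param space A knowledge space.
#' @export
service_priority <- function(space, service_name) {
  df <- space$partitions$policies
  nodes <- df$s[df$p == "forService" & df$o == service_name]
  if (!length(nodes)) return(0)
  sum(vapply(nodes, function(nd)
    as.numeric(.node_field(df, nd, "rewardValue")), 0))
}

#' Reuse a recorded workflow for a transferable context
#'
#' Composition transfer: when a new task matches a recorded success at
#' \code{TRANSFERABLE} level (same input kind, domain and desired output,
#' different dataset), the highest-ranked recorded workflow is re-executed
#' on the new payload — every stage retrained on the new data — without
#' invoking the planner. The outcome is recorded as a new policy for the
#' new context.
#'
#' @param space A knowledge space.
#' @param new_ctx The new \code{task_context}.
#' @param payload [sf_payload()] for the new dataset.
#' @param seed Integer seed.
#' @param params Per-service parameters (see [execute_workflow()]).
#' @param solution_store Optional solution directory.
#' @return List with \code{space}, \code{trace}, \code{outcome},
#'   \code{record} and \code{source} (the reused policy record).
#' @export
transfer_solution <- function(space, new_ctx, payload, seed = 1L,
                              params = list(), solution_store = NULL) {
  hits <- lookup_policy(space, new_ctx)
  hits <- Filter(function(h) h$level == "TRANSFERABLE" &&
                   h$record$state == 1L, hits)
  if (!length(hits)) {
    stop("no prior knowledge: no transferable successful policy for this ",
         "context", call. = FALSE)
  }
  src <- hits[[1]]$record
  trace <- execute_workflow(src$workflow, payload, space, seed = seed,
                            params = params)
  outcome <- evaluate_outcome(trace, new_ctx, solution_store)
  rec <- record_outcome(space, new_ctx, trace, outcome)
  list(space = rec$space, trace = trace, outcome = outcome,
       record = rec$record, source = src)
}

#' Offline continuous update of preferred-solution markers
#'
#' For each distinct context with recorded policies, marks the policy with
#' the highest solution reward (ties broken toward the most recent) as the
#' context's preferred solution. Markers are re-derived from scratch, so the
#' operation is idempotent.
#'
#' @param space A knowledge space.
#' @return The updated space.
#' @export
continuous_update <- function(space) {
  df <- space$partitions$policies
  df <- df[df$p != "prefersSolution", , drop = FALSE]
  ids <- unique(df$s[df$p == "a" & df$o == "PolicyRecord"])
  markers <- list()
  if (length(ids)) {
    recs <- lapply(ids, policy_from_triples, space = space)
    ctxs <- vapply(recs, function(r) r$context_ref, "")
    for (cx in unique(ctxs)) {
      sub <- recs[ctxs == cx]
      rw <- vapply(sub, function(r) r$solution_reward, 0)
      sq <- vapply(sub, function(r) r$seq, 0)
      best <- sub[[order(-rw, -sq)[1]]]
      markers[[length(markers) + 1L]] <-
        triple(cx, "prefersSolution", best$id)
    }
  }
  space$partitions$policies <- df
  if (length(markers)) {
    space <- ks_add_triples(space, "policies", do.call(rbind, markers))
  }
  space
}

#' Preferred solution marker for a context
#' @param space A knowledge space.
#' @param ctx A \code{task_context}.
#' @return Policy identifier, or \code{NULL} when no marker exists.
#' @export
preferred_solution <- function(space, ctx) {
  df <- space$partitions$policies
  v <- df$o[df$s == context_id(ctx) & df$p == "prefersSolution"]
  if (length(v)) v[[1]] else NULL
}

#' @export
print.policy_record <- function(x, ...) {
  cat(sprintf("<policy %s> state=%d reward=%.3f  %s\n", x$id, x$state,
              x$solution_reward, format(x$workflow)))
  invisible(x)
}
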