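# Shared fixtures and independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal valid nine-parameter registration record.
make_record <- function(name, in_kind = "csv_path",
                        out_kind = "labeled_table",
                        category = "data processing", deps = list()) {
  list(name = name, description = paste("test service", name),
       framework = "R", dependencies = deps,
       inputs = list(port("input", in_kind)),
       outputs = list(port("output", out_kind)),
       category = category, license = "MIT",
       invoke_path = paste0("builtin:", name))
}

# Random triple whose identifiers stress escaping (spaces, quotes, unicode).
random_triple <- function() {
  rand_id <- function() {
    pool <- c(letters, LETTERS, 0:9, " ", "_", "-", ".", "\"", "\\", "#",
              "/", ":")
    paste(sample(pool, sample(1:12, 1), replace = TRUE), collapse = "")
  }
  obj <- switch(sample(4, 1),
                rand_id(),
                lit(rand_id()),
                lit(stats::rnorm(1)),
                lit(sample(c(TRUE, FALSE), 1)))
  triple(rand_id(), rand_id(), obj)
}

random_space <- function(n_triples = 50) {
  space <- knowledge_space()
  for (i in seq_len(n_triples)) {
    space <- ks_add_triples(space, sample(c("services", "contexts",
                                            "policies", "world"), 1),
                            random_triple())
  }
  space
}

# Independent linear-scan oracle for ks_match: walks each partition row by
# row instead of vectorised filtering.
scan_match <- function(space, partition, subject, predicate, object) {
  parts <- if (identical(partition, "ALL")) {
    c("services", "contexts", "policies", "world")
  } else partition
  o <- NULL
  if (!is.null(object)) {
    tr <- triple("x", "x", object)
    o <- c(tr$o, tr$o_kind)
  }
  rows <- list()
  for (pn in parts) {
    df <- space$partitions[[pn]]
    for (i in seq_len(nrow(df))) {
      if (!is.null(subject) && df$s[i] != subject) next
      if (!is.null(predicate) && df$p[i] != predicate) next
      if (!is.null(o) && !(df$o[i] == o[1] && df$o_kind[i] == o[2])) next
      r <- df[i, , drop = FALSE]
      r$partition <- pn
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (!length(rows)) {
    out <- space$partitions[[parts[1]]][0, , drop = FALSE]
    out$partition <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$s, out$p, out$o, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Independent brute-force enumeration of simple service chains from kind
# `from` to kind `to`: breadth-first growth of partial chains, no service
# reused, length capped. Returns the set of chains as "a|b|c" strings.
enumerate_chains <- function(services, from, to, max_depth = 8L) {
  # services: data.frame with columns name, in_kind, out_kind
  done <- character(0)
  frontier <- list(list(kind = from, steps = character(0)))
  while (length(frontier)) {
    nxt <- list()
    for (st in frontier) {
      if (length(st$steps) > 0L && st$kind == to) {
        done <- c(done, paste(st$steps, collapse = "|"))
      }
      if (length(st$steps) >= max_depth) next
      for (i in seq_len(nrow(services))) {
        if (services$in_kind[i] == st$kind &&
            !(services$name[i] %in% st$steps)) {
          nxt[[length(nxt) + 1L]] <- list(kind = services$out_kind[i],
                                          steps = c(st$steps,
                                                    services$name[i]))
        }
      }
    }
    frontier <- nxt
  }
  sort(unique(done))
}

# Random registry over a small kind alphabet, for completeness checks.
random_registry <- function(n_services, kinds) {
  space <- knowledge_space()
  tbl <- data.frame(name = character(0), in_kind = character(0),
                    out_kind = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(n_services)) {
    ik <- sample(kinds, 1)
    ok <- sample(kinds, 1)
    nm <- sprintf("svc%02d", i)
    space <- register_service(space, make_record(nm, ik, ok))$space
    tbl <- rbind(tbl, data.frame(name = nm, in_kind = ik, out_kind = ok,
                                 stringsAsFactors = FALSE))
  }
  list(space = space, table = tbl)
}

random_context <- function() {
  kinds <- data_kinds()
  ik <- sample(kinds, 1)
  ok <- sample(setdiff(kinds, ik), 1)
  ncol <- sample(1:12, 1)
  preview <- as.data.frame(matrix(stats::rnorm(5 * ncol), 5, ncol))
  names(preview) <- paste0("col ", sample(1000, ncol))
  build_context(ik, paste0("domain", sample(50, 1)), ok, preview)
}

# Synthetic execution trace over named steps, `n_ok` of which succeeded.
make_trace <- function(steps, n_ok = length(steps), seed = 1L) {
  n <- length(steps)
  status <- rep("skipped", n)
  if (n_ok > 0) status[seq_len(n_ok)] <- "succeeded"
  failure_index <- NA_integer_
  if (n_ok < n) {
    failure_index <- n_ok + 1L
    status[failure_index] <- "failed"
  }
  final <- if (n_ok == n) sf_payload("optimized_model", list()) else NULL
  structure(list(workflow = workflow(steps), step_status = status,
                 failure_index = failure_index, final_output = final,
                 metrics = list(), error = NULL, seed = seed,
                 feature_reuse = FALSE),
            class = "execution_trace")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

heart_context <- function(n_rows = 335L, seed = 1L) {
  h <- make_heartlike_table(n_rows, seed = seed)
  build_context("csv_path", "medical", "optimized_model", h$table)
}
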