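test_that("single-service matching answers the three canonical cases", {
  s3 <- scenario_registry()
  cm <- make_count_matrix(n_cells = 60, n_genes = 80, seed = 1)
  ctx <- build_context("counts_csv_path", "single-cell biology",
                       "cluster_labels", as.data.frame(cm$matrix$counts),
                       modality = "counts")
  # no single service takes the counts CSV to cluster labels
  expect_length(find_single_service(ctx, s3), 0L)

  direct <- register_service(s3, make_record("oneshot", "counts_csv_path",
                                             "cluster_labels"))$space
  hit <- find_single_service(ctx, direct)
  expect_identical(names(hit), "oneshot")

  expect_length(find_single_service(ctx, knowledge_space()), 0L)
})

test_that("the tabular scenario composes the four-stage chain first", {
  ctx <- heart_context(100, seed = 1)
  cands <- compose(ctx, default_registry())
  expect_gt(length(cands), 0L)
  expect_identical(cands[[1]]$steps,
                   c("csv_loader", "data_splitter", "classifier_pipeline",
                     "rfecv_optimizer"))
  expect_length(cands[[1]]$steps, 4L)
})

test_that("the single-cell scenario composes five-stage chains", {
  s3 <- scenario_registry()
  cm <- make_count_matrix(n_cells = 60, n_genes = 80, seed = 1)
  ctx <- build_context("counts_csv_path", "single-cell biology",
                       "cluster_labels", as.data.frame(cm$matrix$counts),
                       modality = "counts")
  cands <- compose(ctx, s3)
  # 3 embedders x 2 clusterers
  expect_length(cands, 6L)
  expect_true(all(vapply(cands, function(w) length(w$steps), 0L) == 5L))
  expect_identical(cands[[1]]$steps[1:3],
                   c("counts_loader", "counts_qc", "counts_normalizer"))
})

test_that("stage preferences prune the candidate set", {
  s3 <- scenario_registry()
  cm <- make_count_matrix(n_cells = 60, n_genes = 80, seed = 1)
  ctx <- build_context("counts_csv_path", "single-cell biology",
                       "cluster_labels", as.data.frame(cm$matrix$counts),
                       modality = "counts")
  cands <- compose(ctx, s3)

  pinned <- apply_preferences(cands, list(embedding = "umap_embedder"), s3)
  expect_length(pinned, 2L)
  expect_true(all(vapply(pinned, function(w)
    "umap_embedder" %in% w$steps, TRUE)))

  both <- apply_preferences(cands,
                            list(embedding = "umap_embedder",
                                 cluster_labels = "louvain_cluster"), s3)
  expect_length(both, 1L)

  expect_identical(apply_preferences(cands, list(), s3), cands)
  expect_error(apply_preferences(cands, list(embedding = "nope"), s3),
               "unregistered")
})

test_that("composition equals brute-force chain enumeration", {
  set.seed(13)
  kinds <- c("csv_path", "labeled_table", "split_data", "embedding")
  for (rep in 1:30) {
    reg <- random_registry(sample(2:8, 1), kinds)
    from <- sample(kinds, 1)
    to <- sample(setdiff(kinds, from), 1)
    preview <- data.frame(x = 1:3, target = c(0, 1, 0))
    ctx <- build_context(from, "test", to, preview)
    got <- sort(vapply(compose(ctx, reg$space), function(w)
      paste(w$steps, collapse = "|"), ""))
    want <- enumerate_chains(reg$table, from, to, max_depth = 8L)
    expect_identical(got, want)
  }
})

test_that("composed workflows satisfy the chain invariants", {
  set.seed(17)
  kinds <- c("csv_path", "labeled_table", "split_data", "embedding")
  for (rep in 1:10) {
    reg <- random_registry(sample(3:8, 1), kinds)
    ctx <- build_context(kinds[1], "test", kinds[4],
                         data.frame(x = 1:3, target = c(0, 1, 0)))
    for (w in compose(ctx, reg$space)) {
      expect_false(anyDuplicated(w$steps) > 0)
      io <- reg$table[match(w$steps, reg$table$name), ]
      expect_identical(io$in_kind[1], ctx$input_kind)
      expect_identical(io$out_kind[nrow(io)], ctx$desired_output_kind)
      if (nrow(io) > 1) {
        expect_identical(io$out_kind[-nrow(io)], io$in_kind[-1])
      }
      expect_true(isTRUE(validate_workflow(w, ctx, reg$space)))
    }
  }
})

test_that("ranking is policy-aware, total and idempotent", {
  s <- default_registry()
  ctx <- heart_context(60, seed = 2)
  cands <- compose(ctx, s)
  # no policy knowledge: pure (length, lexicographic) order
  ranked0 <- rank_workflows(cands, s)
  lens <- vapply(ranked0, function(w) length(w$steps), 0L)
  expect_true(all(diff(lens) >= 0))

  # reward one service of the longer chain: it outranks its equal-length peer
  two <- list(workflow(c("a_svc", "x_mid", "z_end")),
              workflow(c("a_svc", "y_mid", "z_end")))
  sp <- knowledge_space()
  tr <- make_trace(c("y_mid", "other"), n_ok = 2)
  sp <- record_outcome(sp, heart_context(40, seed = 1), tr,
                       list(state = 1L, solution_iloc = NULL,
                            metric = NULL))$space
  ranked <- rank_workflows(two, sp)
  expect_identical(ranked[[1]]$steps[2], "y_mid")

  # idempotence and permutation on random candidate sets
  set.seed(23)
  for (rep in 1:5) {
    nm <- replicate(6, paste(sample(letters, 5), collapse = ""))
    cs <- lapply(1:6, function(i)
      workflow(sample(nm, sample(2:5, 1))))
    r1 <- rank_workflows(cs, sp)
    r2 <- rank_workflows(r1, sp)
    expect_identical(r1, r2)
    expect_setequal(vapply(r1, format, ""), vapply(cs, format, ""))
  }
})

test_that("planner invocations are counted and resettable", {
  reset_planner_calls()
  expect_identical(planner_call_count(), 0L)
  ctx <- heart_context(40, seed = 1)
  invisible(compose(ctx, default_registry()))
  expect_identical(planner_call_count(), 1L)
  reset_planner_calls()
  expect_identical(planner_call_count(), 0L)
})
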