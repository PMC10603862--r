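ctx_a <- function() heart_context(100, seed = 1)

test_that("success distributes reward 1/n to every step", {
  steps <- c("csv_loader", "data_splitter", "classifier_pipeline",
             "rfecv_optimizer")
  sp <- knowledge_space()
  res <- record_outcome(sp, ctx_a(), make_trace(steps),
                        list(state = 1L, solution_iloc = tempfile(),
                             metric = 0.9))
  r <- res$record
  expect_identical(r$state, 1L)
  expect_equal(unname(r$step_rewards), rep(0.25, 4))
  expect_equal(sum(r$step_rewards), 1)
  expect_false(is.null(r$solution_iloc))
})

test_that("failures reward only the m steps that completed", {
  steps <- c("a", "b", "c", "d")
  sp <- knowledge_space()
  res <- record_outcome(sp, ctx_a(), make_trace(steps, n_ok = 3),
                        list(state = 0L, solution_iloc = NULL,
                             metric = NULL))
  r <- res$record
  expect_identical(r$state, 0L)
  expect_named(r$step_rewards, c("a", "b", "c"))
  expect_equal(unname(r$step_rewards), rep(1 / 3, 3))
  expect_null(r$solution_iloc)

  res0 <- record_outcome(sp, ctx_a(), make_trace(steps, n_ok = 0),
                         list(state = 0L, solution_iloc = NULL,
                              metric = NULL))
  expect_length(res0$record$step_rewards, 0L)
})

test_that("policy records round-trip through the triple store", {
  sp <- knowledge_space()
  res <- record_outcome(sp, ctx_a(),
                        make_trace(c("x", "y"), n_ok = 2),
                        list(state = 1L, solution_iloc = "/tmp/sol",
                             metric = 0.87))
  back <- policy_from_triples(res$space, res$record$id)
  expect_identical(back$state, res$record$state)
  expect_identical(back$workflow$steps, c("x", "y"))
  expect_equal(back$step_rewards, res$record$step_rewards)
  expect_equal(back$metric, 0.87)
  expect_identical(back$solution_iloc, "/tmp/sol")

  # and through full serialisation
  sp2 <- ks_parse(ks_serialize(res$space, "ntriples"), "ntriples")
  expect_equal(policy_from_triples(sp2, res$record$id)$step_rewards,
               res$record$step_rewards)
})

test_that("policy lookup respects match level, reward and recency", {
  sp <- knowledge_space()
  expect_length(lookup_policy(sp, ctx_a()), 0L)

  steps <- c("csv_loader", "data_splitter", "classifier_pipeline",
             "rfecv_optimizer")
  sp <- record_outcome(sp, ctx_a(), make_trace(steps),
                       list(state = 1L, solution_iloc = "/tmp/s1",
                            metric = 0.8))$space
  hits <- lookup_policy(sp, heart_context(250, seed = 42))
  expect_length(hits, 1L)
  expect_identical(hits[[1]]$level, "EXACT")

  pk <- make_classification_table(
    n_rows = 90,
    informative = stats::setNames(c(1, 1), c("updrs1", "updrs2")),
    n_noise = 3, seed = 5)
  pctx <- build_context("csv_path", "medical", "optimized_model", pk$table)
  hits2 <- lookup_policy(sp, pctx)
  expect_length(hits2, 1L)
  expect_identical(hits2[[1]]$level, "TRANSFERABLE")

  # higher-reward policies rank first within a level
  sp <- record_outcome(sp, ctx_a(), make_trace(steps, n_ok = 2),
                       list(state = 0L, solution_iloc = NULL,
                            metric = NULL))$space
  hits3 <- lookup_policy(sp, ctx_a())
  expect_identical(hits3[[1]]$record$state, 1L)
})

test_that("service priority accumulates across records", {
  sp <- knowledge_space()
  expect_equal(service_priority(sp, "never_used"), 0)

  sp <- record_outcome(sp, ctx_a(),
                       make_trace(c("w", "x", "y", "z")),
                       list(state = 1L, solution_iloc = "/tmp/a",
                            metric = NULL))$space
  expect_equal(service_priority(sp, "w"), 0.25)

  # one failed run where w was among the 2 surviving steps: + 1/2
  sp <- record_outcome(sp, ctx_a(),
                       make_trace(c("w", "v", "u"), n_ok = 2),
                       list(state = 0L, solution_iloc = NULL,
                            metric = NULL))$space
  expect_equal(service_priority(sp, "w"), 0.5 + 0.25)
})

test_that("transfer re-executes the recorded workflow without planning", {
  s <- default_registry()
  cfg <- run_config(seed = 5, top_k = 1)
  h <- make_heartlike_table(150, seed = 1)
  tf <- tempfile(fileext = ".csv")
  write_fixture_csv(h$table, tf)
  r1 <- run_task("csv_path", "medical", "optimized_model", tf, s, cfg)
  sp <- r1$space
  recorded <- r1$report$chosen$workflow$steps

  pk <- make_classification_table(
    n_rows = 140,
    informative = stats::setNames(c(1.3, 1.1, 0.9), paste0("updrs", 1:3)),
    n_noise = 6, seed = 2)
  tf2 <- tempfile(fileext = ".csv")
  write_fixture_csv(pk$table, tf2)
  pctx <- build_context("csv_path", "medical", "optimized_model", pk$table)

  reset_planner_calls()
  tr <- transfer_solution(sp, pctx, sf_payload("csv_path", tf2), seed = 5)
  expect_identical(planner_call_count(), 0L)
  expect_identical(tr$trace$workflow$steps, recorded)
  expect_identical(tr$record$context_ref, context_id(pctx))
  expect_gt(ks_size(tr$space, "policies"), ks_size(sp, "policies"))

  # incompatible desired output: no prior knowledge
  other <- build_context("csv_path", "medical", "classification_model",
                         pk$table)
  expect_error(transfer_solution(sp, other, sf_payload("csv_path", tf2)),
               "no prior knowledge")
})

test_that("transfer prefers the higher-reward recorded solution", {
  sp <- knowledge_space()
  sp <- register_service(sp, make_record("fastpath", "csv_path",
                                         "labeled_table"))$space
  sp <- register_service(sp, make_record("slowpath", "csv_path",
                                         "labeled_table"))$space
  register_callable("builtin:fastpath", function(v, p, s) {
    out <- utils::read.csv(v, check.names = FALSE)
    attr(out, "sf_metrics") <- list(accuracy = 1)
    out
  })
  register_callable("builtin:slowpath", function(v, p, s)
    utils::read.csv(v, check.names = FALSE))

  src_ctx <- heart_context(80, seed = 1)
  src_ctx$desired_output_kind <- "labeled_table"
  sp <- record_outcome(sp, src_ctx, make_trace("slowpath"),
                       list(state = 1L, solution_iloc = "/tmp/lo",
                            metric = 0.5))$space
  sp <- record_outcome(sp, src_ctx, make_trace("fastpath"),
                       list(state = 1L, solution_iloc = "/tmp/hi",
                            metric = 1.0))$space

  pk <- make_classification_table(n_rows = 60, seed = 9)
  tfp <- tempfile(fileext = ".csv")
  write_fixture_csv(pk$table, tfp)
  new_ctx <- build_context("csv_path", "medical", "labeled_table", pk$table)
  tr <- transfer_solution(sp, new_ctx, sf_payload("csv_path", tfp))
  expect_identical(tr$source$workflow$steps, "fastpath")
})

test_that("continuous update marks the argmax policy per context and is idempotent", {
  sp <- knowledge_space()
  c1 <- heart_context(80, seed = 1)
  sp <- record_outcome(sp, c1, make_trace(c("a", "b")),
                       list(state = 1L, solution_iloc = "/tmp/1",
                            metric = 0.4))$space
  sp <- record_outcome(sp, c1, make_trace(c("a", "c")),
                       list(state = 1L, solution_iloc = "/tmp/2",
                            metric = 0.9))$space
  up1 <- continuous_update(sp)
  best <- preferred_solution(up1, c1)
  expect_identical(policy_from_triples(up1, best)$metric, 0.9)

  up2 <- continuous_update(up1)
  expect_true(ks_equal(up1, up2))

  # randomized stores: marker equals a brute-force argmax
  set.seed(31)
  sp2 <- knowledge_space()
  ctxs <- replicate(3, random_context(), simplify = FALSE)
  recs <- list()
  for (i in 1:12) {
    cx <- sample(ctxs, 1)[[1]]
    m <- runif(1)
    sp2 <- record_outcome(sp2, cx, make_trace(c("s1", "s2")),
                          list(state = 1L, solution_iloc = "/tmp/x",
                               metric = m))$space
  }
  up <- continuous_update(sp2)
  for (cx in ctxs) {
    ids <- policy_ids(up)
    rs <- lapply(ids, policy_from_triples, space = up)
    mine <- Filter(function(r) r$context_ref == context_id(cx), rs)
    if (!length(mine)) next
    rw <- vapply(mine, function(r) r$solution_reward, 0)
    sq <- vapply(mine, function(r) r$seq, 0)
    want <- mine[[order(-rw, -sq)[1]]]$id
    expect_identical(preferred_solution(up, cx), want)
  }
})
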