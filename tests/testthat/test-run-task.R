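fresh_store <- function() {
  opt <- options(semflow.solution_store = file.path(tempfile(), "sol"))
  opt
}

test_that("a first task plans, executes and records; a rerun reuses exactly", {
  s <- default_registry()
  cfg <- run_config(seed = 5, top_k = 1)
  h <- make_heartlike_table(150, seed = 1)
  tf <- tempfile(fileext = ".csv")
  write_fixture_csv(h$table, tf)

  reset_planner_calls()
  r1 <- run_task("csv_path", "medical", "optimized_model", tf, s, cfg)
  expect_identical(r1$report$route, "plan")
  expect_true(r1$report$planner_invoked)
  expect_identical(planner_call_count(), 1L)
  expect_length(r1$report$chosen$workflow$steps, 4L)
  expect_gt(r1$report$knowledge_written, 0L)
  expect_gt(ks_size(r1$space), ks_size(s))

  # identical resubmission: exact policy hit, no planning
  reset_planner_calls()
  r2 <- run_task("csv_path", "medical", "optimized_model", tf,
                 r1$space, cfg)
  expect_identical(r2$report$route, "exact")
  expect_false(r2$report$planner_invoked)
  expect_identical(planner_call_count(), 0L)
  expect_identical(r2$report$chosen$workflow$steps,
                   r1$report$chosen$workflow$steps)
})

test_that("a schema-different same-domain task takes the transfer route", {
  s <- default_registry()
  cfg <- run_config(seed = 5, top_k = 1)
  h <- make_heartlike_table(150, seed = 1)
  tf <- tempfile(fileext = ".csv")
  write_fixture_csv(h$table, tf)
  r1 <- run_task("csv_path", "medical", "optimized_model", tf, s, cfg)

  pk <- make_classification_table(
    n_rows = 140,
    informative = stats::setNames(c(1.3, 1.0, 0.9), paste0("updrs", 1:3)),
    n_noise = 6, seed = 3)
  tf2 <- tempfile(fileext = ".csv")
  write_fixture_csv(pk$table, tf2)

  reset_planner_calls()
  r3 <- run_task("csv_path", "medical", "optimized_model", tf2,
                 r1$space, cfg)
  expect_identical(r3$report$route, "transfer")
  expect_identical(planner_call_count(), 0L)
  expect_identical(r3$report$executed[[1]]$workflow$steps,
                   r1$report$chosen$workflow$steps)
  expect_identical(r3$report$executed[[1]]$state, 1L)
  # every run appends policy knowledge: the store strictly grows
  expect_gt(ks_size(r3$space), ks_size(r1$space))
})

test_that("an impossible request records a failure policy with no steps", {
  s <- default_registry()
  h <- make_heartlike_table(60, seed = 1)
  tf <- tempfile(fileext = ".csv")
  write_fixture_csv(h$table, tf)
  r <- run_task("csv_path", "medical", "image_label", tf, s,
                run_config(seed = 1))
  expect_identical(r$report$route, "failure")
  expect_length(r$report$executed, 1L)
  expect_identical(r$report$executed[[1]]$state, 0L)
  rec <- policy_from_triples(r$space, r$report$executed[[1]]$policy)
  expect_length(rec$workflow$steps, 0L)
  expect_length(rec$step_rewards, 0L)
  expect_gt(ks_size(r$space, "policies"), 0L)
})

test_that("dry runs rank candidates without writing knowledge", {
  s <- scenario_registry()
  cm <- make_count_matrix(n_cells = 60, n_genes = 80, seed = 2)
  tf <- tempfile(fileext = ".csv")
  write_fixture_csv(cm$matrix, tf)
  r <- run_task("counts_csv_path", "single-cell biology", "cluster_labels",
                tf, s, run_config(seed = 1), dry_run = TRUE,
                prefs = list(embedding = "umap_embedder"))
  expect_identical(r$report$route, "plan")
  expect_length(r$report$candidates, 2L)
  expect_length(r$report$executed, 0L)
  expect_identical(ks_size(r$space), ks_size(s))
})

test_that("config files load with validation", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "max_depth: 6", "cv_folds: 4"), tf)
  cfg <- load_run_config(tf)
  expect_identical(cfg$seed, 9L)
  expect_identical(cfg$max_depth, 6L)
  writeLines("bogus_key: 1", tf)
  expect_error(load_run_config(tf), "unknown config keys")
})

test_that("the command-line entry point plans a task", {
  cli <- system.file("cli", "semflow.R", package = "semflow")
  skip_if(cli == "", "CLI script not installed")
  h <- make_heartlike_table(80, seed = 1)
  tf <- tempfile(fileext = ".csv")
  write_fixture_csv(h$table, tf)
  req <- tempfile(fileext = ".yaml")
  writeLines(c("input_kind: csv_path", "domain: medical",
               "desired_output_kind: optimized_model"), req)
  out <- suppressWarnings(
    system2("Rscript", c(cli, "submit", req, "--data", tf, "--dry-run"),
            stdout = TRUE, stderr = TRUE))
  expect_identical(attr(out, "status") %||% 0L, 0L)
  expect_true(any(grepl("rfecv_optimizer", out)))
})
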