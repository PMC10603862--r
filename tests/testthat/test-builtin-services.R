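test_that("CSV loading enforces schema and types", {
  h <- make_heartlike_table(60, seed = 1)$table
  tf <- tempfile(fileext = ".csv")
  write_fixture_csv(h, tf)
  tab <- svc_csv_load(tf)
  expect_identical(ncol(tab), 14L)
  expect_true("target" %in% names(tab))

  nolabel <- h[, setdiff(names(h), "target")]
  tf2 <- tempfile(fileext = ".csv")
  write_fixture_csv(nolabel, tf2)
  expect_error(svc_csv_load(tf2), "label")

  cm <- make_count_matrix(n_cells = 40, n_genes = 60, seed = 1)
  tf3 <- tempfile(fileext = ".csv")
  write_fixture_csv(cm$matrix, tf3)
  m <- svc_load_counts(tf3)
  expect_identical(dim(m$counts), c(40L, 60L))
})

test_that("splitting is stratified, seeded and arithmetic-exact", {
  d <- make_classification_table(n_rows = 100, seed = 2)$table
  sp <- svc_split(d, list(ratio = 0.8), seed = 3)
  expect_identical(nrow(sp$train), 80L)
  expect_identical(nrow(sp$test), 20L)
  expect_identical(svc_split(d, list(ratio = 0.8), seed = 3)$train, sp$train)

  # class proportions preserved within one row
  for (cl in 0:1) {
    n_cl <- sum(d$target == cl)
    expect_lte(abs(sum(sp$train$target == cl) - 0.8 * n_cl), 1)
  }
  single <- d[d$target == d$target[1], ]
  expect_error(svc_split(single, list(ratio = 0.8), 1), "single-class")
})

test_that("table QC drops incomplete rows and dead features", {
  d <- make_classification_table(n_rows = 50, seed = 3)$table
  d$inf1[c(4, 9)] <- NA
  d$flatline <- 1
  out <- svc_table_qc(d)
  expect_identical(nrow(out), 48L)
  expect_false("flatline" %in% names(out))
})

test_that("counts QC removes exactly the planted low-depth cells", {
  cm <- make_count_matrix(n_cells = 200, n_genes = 300, seed = 4)
  out <- svc_counts_qc(cm$matrix, list(depth_percentile = 5))
  removed <- setdiff(rownames(cm$matrix$counts), rownames(out$counts))
  expect_setequal(removed, cm$lowdepth_cells)

  # an all-zero gene never survives
  m <- cm$matrix
  m$counts[, 7] <- 0L
  out2 <- svc_counts_qc(m)
  expect_false(colnames(cm$matrix$counts)[7] %in% colnames(out2$counts))
})

test_that("normalisation obeys its contracts", {
  d <- make_classification_table(n_rows = 60, seed = 5)$table
  z <- svc_table_normalize(d)
  expect_equal(mean(z$inf1), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$inf1), 1, tolerance = 1e-12)
  # idempotent
  expect_equal(svc_table_normalize(z), z, tolerance = 1e-12)
  d$flat <- 2
  expect_error(svc_table_normalize(d), "zero-variance")

  cm <- make_count_matrix(n_cells = 80, n_genes = 120, seed = 6)
  qc <- svc_counts_qc(cm$matrix)
  nm <- svc_counts_normalize(qc)
  med <- stats::median(rowSums(qc$counts))
  expect_equal(unname(rowSums(expm1(nm))), rep(med, nrow(nm)),
               tolerance = 1e-6)
})

test_that("the classifier nails separable data and flounders on noise", {
  set.seed(7)
  n <- 200
  x <- stats::rnorm(n)
  x <- x + 0.4 * sign(x)   # margin-separated classes
  sep <- data.frame(f1 = x, f2 = stats::rnorm(n), target = as.integer(x > 0))
  sp <- svc_split(sep, list(ratio = 0.7), seed = 1)
  m <- svc_classify(sp, list(), seed = 1)
  expect_equal(m$accuracy, 1.0)

  shuffled <- sep
  shuffled$target <- sample(shuffled$target)
  sp2 <- svc_split(shuffled, list(ratio = 0.7), seed = 1)
  m2 <- svc_classify(sp2, list(), seed = 1)
  expect_lt(abs(m2$accuracy - 0.5), 0.15)  # binomial CI at n = 60

  m3 <- svc_classify(sp, list(), seed = 1)
  expect_identical(m$importance, m3$importance)
})

test_that("feature elimination scores every subset size and keeps signal", {
  d <- make_classification_table(
    n_rows = 200,
    informative = stats::setNames(c(1.5, 1.2), c("s1", "s2")),
    n_noise = 0, seed = 8)
  sp <- svc_split(d$table, list(ratio = 0.8), seed = 1)
  m <- svc_classify(sp, list(), seed = 1)
  opt <- svc_optimize(m, list(folds = 5), seed = 1)
  expect_setequal(opt$selected_features, c("s1", "s2"))
  expect_identical(nrow(opt$cv_curve), 2L)  # p down to 1

  d2 <- make_classification_table(n_rows = 150, n_noise = 6, seed = 9)
  sp2 <- svc_split(d2$table, list(ratio = 0.8), seed = 1)
  opt2 <- svc_optimize(svc_classify(sp2, list(), 1), list(folds = 5), 1)
  expect_identical(nrow(opt2$cv_curve), 11L)
  expect_identical(opt2$cv_curve$n_features, 11:1)
})

test_that("PCA embedding matches an eigendecomposition oracle", {
  set.seed(10)
  x <- matrix(stats::rnorm(40), 10, 4)
  e <- svc_embed_pca(x, list(dims = 3))
  # oracle: eigenvectors of the covariance of centred data
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc))
  oracle <- xc %*% ev$vectors[, 1:3]
  for (j in 1:3) {
    expect_equal(abs(e[, j]), abs(oracle[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # explained variance non-increasing
  expect_true(all(diff(attr(e, "sdev")) <= 1e-12))

  # exact low-rank reconstruction
  base <- matrix(stats::rnorm(20), 10, 2)
  lowrank <- base %*% matrix(stats::rnorm(10), 2, 5)
  e2 <- svc_embed_pca(lowrank, list(dims = 2))
  sd_rest <- attr(e2, "sdev")[3:5]
  expect_lt(max(sd_rest), 1e-10)
  expect_error(svc_embed_pca(x, list(dims = 4)), "dims")
})

test_that("clustering recovers planted blobs", {
  set.seed(12)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  truth <- rep(1:3, each = 40)
  pts <- centers[truth, ] + matrix(stats::rnorm(240, sd = 0.5), 120, 2)
  rownames(pts) <- paste0("p", 1:120)

  km <- svc_cluster_kmeans(pts, list(k = 3), seed = 1)
  expect_gte(ari(km, truth), 0.99)
  expect_length(km, 120L)
  expect_error(svc_cluster_kmeans(pts[1:2, ], list(k = 5), 1), "exceeds")

  gr <- svc_cluster_graph(pts, list(neighbors = 15), seed = 1)
  expect_gte(ari(gr, truth), 0.9)

  # duplicated points always share a label
  dup <- rbind(pts, pts[1:10, ])
  km2 <- svc_cluster_kmeans(dup, list(k = 3), seed = 1)
  expect_identical(unname(km2[1:10]), unname(km2[121:130]))
})

test_that("optional embedding backends work when present, error clearly when not", {
  x <- matrix(stats::rnorm(750), 150, 5)
  if (requireNamespace("Rtsne", quietly = TRUE)) {
    e <- svc_embed_tsne(x, list(dims = 2), seed = 1)
    expect_identical(dim(e), c(150L, 2L))
  } else {
    expect_error(svc_embed_tsne(x), "Rtsne")
  }
  if (requireNamespace("uwot", quietly = TRUE)) {
    e <- svc_embed_umap(x, list(dims = 2), seed = 1)
    expect_identical(dim(e), c(150L, 2L))
  } else {
    expect_error(svc_embed_umap(x), "uwot")
  }
})

test_that("descriptor ports agree with their callables", {
  # registry-implementation conformance: every registered builtin resolves
  # to a callable, and running the declared chains type-checks end to end
  s <- scenario_registry()
  for (d in registry_descriptors(s)) {
    expect_true(startsWith(d$invoke_path, "builtin:"))
    expect_silent(semflow:::.resolve_callable(d$invoke_path))
  }
})

test_that("the pipeline preserves the set of planted classes", {
  cm <- make_count_matrix(n_cells = 150, n_genes = 200, seed = 13)
  qc <- svc_counts_qc(cm$matrix)
  nm <- svc_counts_normalize(qc)
  e <- svc_embed_pca(nm, list(dims = 10))
  surviving <- cm$labels[rownames(e)]
  expect_setequal(unique(surviving), unique(cm$labels))
})
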