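#' @title Built-in microservices
#'
#' @description The concrete services that initialise the environment. Each
#' service is a pure function of \code{(value, params, seed)} registered as
#' an in-process callable under an invoke path of the form
#' \code{builtin:<name>}, with a matching nine-parameter descriptor. Three
#' groups are provided: data-processing services (CSV loading, stratified
#' splitting, quality control, normalisation), ML services (PCA embedding,
#' k-means clustering, regularised logistic classification) and the
#' RFE-with-CV optimisation service. Four extra services for the single-cell
#' scenario (count-matrix loading, t-SNE/UMAP embedding, graph clustering)
#' are added by [scenario_registry()].
#'
#' Port kinds are stage-distinct for the single-cell pipeline
#' (\code{counts_csv_path} through \code{count_matrix},
#' \code{qc_count_matrix}, \code{normalized_matrix}, \code{embedding} to
#' \code{cluster_labels}) so the minimal admissible clustering chain has
#' exactly five stages.
#'
#' @name builtin_services
NULL

# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.label_col <- function(params) params$label %||% "target"

.feature_cols <- function(df, label) setdiff(names(df), label)

# -- data processing ----------------------------------------------------------

#' Load a labelled CSV table
#'
#' @param path Path to a CSV file with numeric feature columns and a binary
#'   label column (default name \code{target}, override via
#'   \code{params$label}).
#' @param params,seed Standard service arguments.
#' @return Data frame (a labelled table).
#' @export
svc_csv_load <- function(path, params = list(), seed = 1L) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  label <- .label_col(params)
  if (!label %in% names(df)) {
    stop("missing label column '", label, "'", call. = FALSE)
  }
  feats <- .feature_cols(df, label)
  bad <- feats[!vapply(df[feats], is.numeric, TRUE)]
  if (length(bad)) {
    stop("non-numeric feature columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Load a cells-by-genes count matrix from CSV
#'
#' First column holds cell identifiers; remaining columns are genes with
#' non-negative integer counts.
#' @inheritParams svc_csv_load
#' @return List with element \code{counts}, an integer matrix with cell row
#'   names and gene column names.
#' @export
svc_load_counts <- function(path, params = list(), seed = 1L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m) || any(m < 0) || any(m != round(m))) {
    stop("count matrix must hold non-negative integers", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  list(counts = m)
}

#' Stratified train/test split
#'
#' @param table Labelled table.
#' @param params \code{ratio} (default 0.8) and \code{label}.
#' @param seed Seed; identical seeds give identical partitions.
#' @return List with \code{train}, \code{test}, \code{ratio}, \code{seed}.
#' @export
svc_split <- function(table, params = list(), seed = 1L) {
  ratio <- params$ratio %||% 0.8
  stopifnot(ratio > 0, ratio < 1)
  label <- .label_col(params)
  y <- table[[label]]
  tab <- table(y)
  if (length(tab) < 2L) stop("single-class input cannot be split",
                             call. = FALSE)
  if (any(tab < 2L)) stop("need at least 2 rows per class", call. = FALSE)
  train_idx <- with_seed(seed, {
    unlist(lapply(names(tab), function(cl) {
      idx <- which(y == cl)
      sample(idx, round(ratio * length(idx)))
    }))
  })
  train_idx <- sort(train_idx)
  list(train = table[train_idx, , drop = FALSE],
       test = table[-train_idx, , drop = FALSE],
       ratio = ratio, seed = seed)
}

#' Quality control for labelled tables
#'
#' Drops rows with any missing value and zero-variance feature columns.
#' @inheritParams svc_split
#' @export
svc_table_qc <- function(table, params = list(), seed = 1L) {
  label <- .label_col(params)
  keep_rows <- stats::complete.cases(table)
  out <- table[keep_rows, , drop = FALSE]
  if (nrow(out) == 0L) stop("no data survives QC", call. = FALSE)
  feats <- .feature_cols(out, label)
  zero_var <- feats[vapply(out[feats], function(v) stats::var(v) == 0, TRUE)]
  out <- out[, setdiff(names(out), zero_var), drop = FALSE]
  if (length(.feature_cols(out, label)) == 0L) {
    stop("no data survives QC", call. = FALSE)
  }
  out
}

#' Quality control for count matrices
#'
#' Removes cells whose total count falls below the q-th percentile of cell
#' totals (default q = 5) and genes detected in fewer than
#' \code{min_cells} cells (default 3).
#'
#' @param x List with element \code{counts} (cells x genes matrix).
#' @param params \code{depth_percentile} (default 5), \code{min_cells}
#'   (default 3).
#' @param seed Unused; present for the uniform service signature.
#' @export
svc_counts_qc <- function(x, params = list(), seed = 1L) {
  q <- params$depth_percentile %||% 5
  min_cells <- params$min_cells %||% 3
  m <- x$counts
  totals <- rowSums(m)
  thr <- stats::quantile(totals, q / 100, names = FALSE)
  m <- m[totals >= thr, , drop = FALSE]
  if (nrow(m) == 0L) stop("no data survives QC", call. = FALSE)
  detected <- colSums(m > 0)
  m <- m[, detected >= min_cells, drop = FALSE]
  if (ncol(m) == 0L) stop("no data survives QC", call. = FALSE)
  list(counts = m)
}

#' Normalise a QC'd count matrix
#'
#' Scales each cell to the median total count, then applies log(1 + x).
#' @param x List with element \code{counts}.
#' @param params,seed Standard service arguments.
#' @return Numeric matrix (cells x genes), log-normalised.
#' @export
svc_counts_normalize <- function(x, params = list(), seed = 1L) {
  m <- x$counts
  totals <- rowSums(m)
  if (any(totals == 0)) stop("cell with zero total reached normalisation",
                             call. = FALSE)
  med <- stats::median(totals)
  log1p(m / totals * med)
}

#' Normalise a labelled table by per-feature z-scoring
#'
#' Each feature column is centred and scaled to unit variance; the label is
#' untouched. Idempotent: re-normalising changes nothing.
#' @inheritParams svc_split
#' @export
svc_table_normalize <- function(table, params = list(), seed = 1L) {
  label <- .label_col(params)
  feats <- .feature_cols(table, label)
  for (f in feats) {
    v <- table[[f]]
    s <- stats::sd(v)
    if (s == 0) stop("zero-variance feature '", f,
                     "' reached normalisation (QC contract violation)",
                     call. = FALSE)
    table[[f]] <- (v - mean(v)) / s
  }
  table
}

# -- classification and optimisation -----------------------------------------

# Fit a regularised (ridge) logistic classifier on `feats`; absolute
# standardised coefficients serve as RFE importances. glmnet needs >= 2
# predictors; a single-feature fit falls back to plain logistic regression.
.fit_linear <- function(train, feats, label, lambda = 1e-2) {
  y <- train[[label]]
  if (length(feats) >= 2L) {
    x <- as.matrix(train[feats])
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = TRUE)
    coefs <- as.numeric(stats::coef(fit))[-1]
    pred <- function(newdata) {
      p <- stats::predict(fit, as.matrix(newdata[feats]), type = "response")
      as.integer(p[, 1] > 0.5)
    }
  } else {
    d <- train[c(feats, label)]
    names(d) <- c("x1", ".y")
    fit <- suppressWarnings(
      stats::glm(.y ~ x1, data = d, family = stats::binomial()))
    coefs <- as.numeric(stats::coef(fit))[-1]
    pred <- function(newdata) {
      nd <- data.frame(x1 = newdata[[feats]])
      as.integer(stats::predict(fit, nd, type = "response") > 0.5)
    }
  }
  list(fit = fit, features = feats,
       importance = stats::setNames(abs(coefs), feats), predict = pred)
}

.accuracy <- function(model, data, label) {
  mean(model$predict(data) == data[[label]])
}

#' Fit a classification pipeline on a train/test split
#'
#' Regularised logistic regression; the fitted model exposes per-feature
#' importance scores (absolute standardised coefficients) and a
#' \code{predict} closure. Test accuracy is attached as a metric.
#'
#' @param split Output of [svc_split()].
#' @param params \code{lambda} (ridge penalty, default 0.01), \code{label}.
#' @param seed Seed (the fit itself is deterministic).
#' @return A classification-model payload: the fitted model plus the split
#'   it was trained on, its features, importances and test accuracy.
#' @export
svc_classify <- function(split, params = list(), seed = 1L) {
  label <- .label_col(params)
  feats <- .feature_cols(split$train, label)
  if (length(unique(split$train[[label]])) < 2L) {
    stop("degenerate train partition: single class", call. = FALSE)
  }
  model <- .fit_linear(split$train, feats, label,
                       lambda = params$lambda %||% 1e-2)
  acc <- .accuracy(model, split$test, label)
  out <- c(model, list(split = split, accuracy = acc, label = label))
  attr(out, "sf_metrics") <- list(accuracy = acc)
  out
}

# Stratified fold assignment, deterministic per seed.
.make_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Recursive feature elimination with cross-validation
#'
#' Starting from the full feature set of the model's training split, repeats:
#' score the current subset by stratified k-fold mean CV accuracy, then drop
#' the feature with the smallest importance magnitude. Every subset size
#' from p down to 1 is scored; the size with maximal mean CV accuracy wins
#' (ties go to fewer features). The final model is refit on the full train
#' partition with the selected subset.
#'
#' @param model A classification-model payload from [svc_classify()] (it
#'   carries the split it was trained on).
#' @param params \code{folds} (default 5), \code{lambda}, \code{label}.
#' @param seed Seed for fold assignment.
#' @return An optimized-model payload: fitted model, selected feature
#'   names, the full CV curve (one row per subset size) and test accuracy.
#' @export
svc_optimize <- function(model, params = list(), seed = 1L) {
  split <- model$split
  label <- model$label %||% .label_col(params)
  k <- params$folds %||% 5
  lambda <- params$lambda %||% 1e-2
  train <- split$train
  feats <- .feature_cols(train, label)
  if (length(feats) < 2L) stop("need at least 2 features", call. = FALSE)
  if (min(table(train[[label]])) < k) {
    stop("folds exceed the smallest class count", call. = FALSE)
  }
  folds <- .make_folds(train[[label]], k, seed)

  cur <- feats
  curve <- list()
  subsets <- list()
  repeat {
    cv_acc <- mean(vapply(seq_len(k), function(f) {
      tr <- train[folds != f, , drop = FALSE]
      te <- train[folds == f, , drop = FALSE]
      m <- .fit_linear(tr, cur, label, lambda)
      .accuracy(m, te, label)
    }, 0))
    curve[[length(curve) + 1L]] <- data.frame(
      n_features = length(cur), mean_cv_accuracy = cv_acc)
    subsets[[length(subsets) + 1L]] <- cur
    if (length(cur) == 1L) break
    m <- .fit_linear(train, cur, label, lambda)
    drop <- names(which.min(m$importance))
    cur <- setdiff(cur, drop)
  }
  curve <- do.call(rbind, curve)
  best <- which(curve$mean_cv_accuracy == max(curve$mean_cv_accuracy))
  best <- best[which.min(curve$n_features[best])]
  selected <- subsets[[best]]

  final <- .fit_linear(train, selected, label, lambda)
  acc <- .accuracy(final, split$test, label)
  out <- c(final, list(selected_features = selected, cv_curve = curve,
                       split = split, accuracy = acc, label = label))
  attr(out, "sf_metrics") <- list(accuracy = acc)
  out
}

#' Replace the optimisation stage with a recorded feature projection
#'
#' Used when world knowledge holds a feature subset for the task's exact
#' table schema: instead of re-running elimination, the classifier is refit
#' on the stored subset. \code{params$features} carries the subset.
#'
#' @inheritParams svc_optimize
#' @export
svc_feature_project <- function(model, params = list(), seed = 1L) {
  features <- params$features
  if (is.null(features)) {
    stop("feature projection requires params$features", call. = FALSE)
  }
  split <- model$split
  label <- model$label %||% .label_col(params)
  missing <- setdiff(features, .feature_cols(split$train, label))
  if (length(missing)) {
    stop("stored features absent from data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  final <- .fit_linear(split$train, features, label,
                       params$lambda %||% 1e-2)
  acc <- .accuracy(final, split$test, label)
  out <- c(final, list(selected_features = features,
                       cv_curve = NULL, split = split,
                       accuracy = acc, label = label, reused = TRUE))
  attr(out, "sf_metrics") <- list(accuracy = acc)
  out
}

# -- embedding and clustering -------------------------------------------------

#' PCA embedding of a normalised matrix
#'
#' @param x Numeric matrix (cells x features).
#' @param params \code{dims} — number of components (default
#'   \code{min(10, ncol - 1)}); must be below the feature count.
#' @param seed Unused (PCA is deterministic up to sign).
#' @return Matrix of cell coordinates (cells x dims).
#' @export
svc_embed_pca <- function(x, params = list(), seed = 1L) {
  dims <- params$dims %||% min(10L, ncol(x) - 1L)
  if (dims >= ncol(x)) stop("dims must be below the feature count",
                            call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  coords <- pc$x[, seq_len(dims), drop = FALSE]
  attr(coords, "sdev") <- pc$sdev
  coords
}

#' t-SNE embedding (optional plug-in)
#'
#' Delegates to the Rtsne package when installed; errors otherwise. PCA is
#' the always-available embedding.
#' @inheritParams svc_embed_pca
#' @export
svc_embed_tsne <- function(x, params = list(), seed = 1L) {
  if (!requireNamespace("Rtsne", quietly = TRUE)) {
    stop("t-SNE embedding requires the optional Rtsne package",
         call. = FALSE)
  }
  dims <- params$dims %||% 2L
  with_seed(seed, Rtsne::Rtsne(x, dims = dims)$Y)
}

#' UMAP embedding (optional plug-in)
#'
#' Delegates to the uwot package when installed; errors otherwise.
#' @inheritParams svc_embed_pca
#' @export
svc_embed_umap <- function(x, params = list(), seed = 1L) {
  if (!requireNamespace("uwot", quietly = TRUE)) {
    stop("UMAP embedding requires the optional uwot package", call. = FALSE)
  }
  dims <- params$dims %||% 2L
  with_seed(seed, uwot::umap(x, n_components = dims))
}

#' k-means clustering of embedded cells
#'
#' @param e Embedding matrix (cells x dims).
#' @param params \code{k} — number of clusters (default 3).
#' @param seed Seed for the initialisation.
#' @return Integer label vector, one per cell.
#' @export
svc_cluster_kmeans <- function(e, params = list(), seed = 1L) {
  k <- params$k %||% 3L
  if (nrow(e) < 2L) stop("need at least 2 points", call. = FALSE)
  if (k > nrow(e)) stop("k exceeds the number of points", call. = FALSE)
  km <- with_seed(seed, stats::kmeans(e, centers = k, nstart = 10L))
  stats::setNames(as.integer(km$cluster), rownames(e))
}

#' Graph clustering of embedded cells
#'
#' Builds a k-nearest-neighbour graph (default 15 neighbours, Euclidean)
#' over the embedding and maximises modularity by the greedy agglomerative
#' algorithm.
#'
#' @param e Embedding matrix (cells x dims).
#' @param params \code{neighbors} (default 15).
#' @param seed Unused (the procedure is deterministic).
#' @return Integer label vector, one per cell.
#' @export
svc_cluster_graph <- function(e, params = list(), seed = 1L) {
  nn <- params$neighbors %||% 15L
  n <- nrow(e)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  nn <- min(nn, n - 1L)
  d <- as.matrix(stats::dist(e))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    ord <- order(d[i, -i])[seq_len(nn)]
    j <- seq_len(n)[-i][ord]
    cbind(i, j)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- igraph::cluster_fast_greedy(g)
  stats::setNames(as.integer(igraph::membership(comm)), rownames(e))
}
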