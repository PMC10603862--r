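#' @title Synthetic fixtures
#'
#' @description Generators for every input the framework's scenarios need,
#' so nothing is downloaded: clinical-style labelled tables with planted
#' informative features (labels drawn from a logistic model on the
#' informative features only, noise features independent of the label), a
#' schema-faithful heart-disease-style table, and cells-by-genes count
#' matrices with planted clusters and planted low-depth cells. All
#' generators are pure functions of their arguments including the seed, and
#' ground truth is returned alongside the data, never written into it.
#'
#' @name synthetic_fixtures
NULL

#' Synthetic labelled classification table
#'
#' Features are independent standard normals. The label is Bernoulli with
#' success probability \code{plogis(intercept + X_inf \%*\% beta)}, where
#' only the informative features enter; the intercept is set from
#' \code{class_balance}.
#'
#' @param n_rows Number of rows (default 500).
#' @param informative Named numeric vector of effect sizes (default five
#'   features with effects 1.5, 1.2, 1.0, 0.9, 0.8).
#' @param n_noise Number of noise features independent of the label
#'   (default 10).
#' @param class_balance Marginal success probability of the label at zero
#'   signal (default 0.5).
#' @param noise_sd Standard deviation of all features (default 1).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return List with \code{table} (data frame with a \code{target} column)
#'   and \code{informative} (the planted feature names).
#' @export
make_classification_table <- function(n_rows = 500L,
                                      informative = stats::setNames(
                                        c(1.5, 1.2, 1.0, 0.9, 0.8),
                                        paste0("inf", 1:5)),
                                      n_noise = 10L,
                                      class_balance = 0.5,
                                      noise_sd = 1,
                                      seed = 1L) {
  stopifnot(n_rows >= 2L, class_balance > 0, class_balance < 1,
            all(is.finite(informative)), !anyDuplicated(names(informative)))
  with_seed(seed, {
    p_inf <- length(informative)
    xi <- matrix(stats::rnorm(n_rows * p_inf, sd = noise_sd), n_rows, p_inf)
    colnames(xi) <- names(informative)
    xn <- NULL
    if (n_noise > 0L) {
      xn <- matrix(stats::rnorm(n_rows * n_noise, sd = noise_sd),
                   n_rows, n_noise)
      colnames(xn) <- paste0("noise", seq_len(n_noise))
    }
    lp <- stats::qlogis(class_balance) +
      if (p_inf > 0L) as.vector(xi %*% informative) else 0
    y <- stats::rbinom(n_rows, 1L, stats::plogis(lp))
    tbl <- as.data.frame(cbind(xi, xn))
    tbl$target <- y
    list(table = tbl, informative = names(informative))
  })
}

HEART_COLUMNS <- c("age", "sex", "cp", "trestbps", "chol", "fbs", "restecg",
                   "thalach", "exang", "oldpeak", "slope", "ca", "thal",
                   "target")

HEART_INFORMATIVE <- c("sex", "cp", "thalach", "exang", "oldpeak", "slope",
                       "ca", "thal")

#' Synthetic heart-disease-style table
#'
#' Emulates the clinical heart-disease CSV schema: exactly the 14 standard
#' columns in order (\code{age} through \code{thal} plus the binary
#' \code{target}), each respecting its clinical encoding (e.g. \code{sex}
#' in \{0, 1\}, \code{slope} in \{0, 1, 2\}, \code{ca} in 0--3). The label
#' depends only on the eight designated informative features (\code{sex},
#' \code{cp}, \code{thalach}, \code{exang}, \code{oldpeak}, \code{slope},
#' \code{ca}, \code{thal}) through a logistic model on their standardised
#' values, so feature-selection results can be compared against that set.
#' This is a synthetic stand-in for the real clinical data, not a
#' reproduction of it.
#'
#' @param n_rows Number of rows (default 335; at least 20).
#' @param seed Integer seed.
#' @return List with \code{table} and \code{informative} (the eight planted
#'   names).
#' @export
make_heartlike_table <- function(n_rows = 335L, seed = 1L) {
  stopifnot(n_rows >= 20L)
  with_seed(seed, {
    df <- data.frame(
      age = sample(29:77, n_rows, replace = TRUE),
      sex = stats::rbinom(n_rows, 1L, 0.68),
      cp = sample(0:3, n_rows, replace = TRUE,
                  prob = c(0.47, 0.17, 0.28, 0.08)),
      trestbps = sample(94:200, n_rows, replace = TRUE),
      chol = sample(126:420, n_rows, replace = TRUE),
      fbs = stats::rbinom(n_rows, 1L, 0.15),
      restecg = sample(0:2, n_rows, replace = TRUE,
                       prob = c(0.49, 0.47, 0.04)),
      thalach = sample(71:202, n_rows, replace = TRUE),
      exang = stats::rbinom(n_rows, 1L, 0.33),
      oldpeak = round(stats::runif(n_rows, 0, 6.2), 1),
      slope = sample(0:2, n_rows, replace = TRUE,
                     prob = c(0.07, 0.46, 0.47)),
      ca = sample(0:3, n_rows, replace = TRUE,
                  prob = c(0.58, 0.22, 0.13, 0.07)),
      thal = sample(0:3, n_rows, replace = TRUE,
                    prob = c(0.02, 0.06, 0.55, 0.37)))
    effects <- stats::setNames(
      c(-0.9, 1.0, 0.9, -0.9, -1.0, 0.8, -1.1, -0.9), HEART_INFORMATIVE)
    z <- scale(as.matrix(df[HEART_INFORMATIVE]))
    lp <- as.vector(z %*% effects)
    df$target <- stats::rbinom(n_rows, 1L, stats::plogis(lp))
    stopifnot(identical(names(df), HEART_COLUMNS))
    list(table = df, informative = HEART_INFORMATIVE)
  })
}

#' Synthetic cells-by-genes count matrix with planted clusters
#'
#' Each cell belongs to one of \code{k_clusters} populations; its counts are
#' multinomial over the population's expression profile with a total drawn
#' from the depth distribution. Profiles are baseline-uniform with a
#' population-specific block of marker genes at elevated weight, so
#' populations are separable. Exactly \code{n_lowdepth} cells are planted
#' with depths far below the rest, landing under the default 5th-percentile
#' quality-control cut.
#'
#' @param n_cells Number of cells (default 200).
#' @param n_genes Number of genes (default 500).
#' @param k_clusters Number of planted populations (default 3).
#' @param proportions Cluster proportions (default equal; must sum to 1).
#' @param marker_genes Markers per cluster (default 40).
#' @param marker_weight Relative expression of a marker in its own cluster
#'   (default 6).
#' @param depth_range Total-count range of normal cells (default
#'   2000--5000).
#' @param lowdepth_range Total-count range of planted low-depth cells
#'   (default 20--60).
#' @param n_lowdepth Number of planted low-depth cells (default 5\% of
#'   cells).
#' @param seed Integer seed.
#' @return List with \code{matrix} (a count-matrix payload,
#'   \code{list(counts = ...)}), \code{labels} (planted cluster of every
#'   cell) and \code{lowdepth_cells} (names of the planted low-depth
#'   cells).
#' @export
make_count_matrix <- function(n_cells = 200L, n_genes = 500L,
                              k_clusters = 3L,
                              proportions = rep(1 / k_clusters, k_clusters),
                              marker_genes = min(40L, n_genes %/% k_clusters),
                              marker_weight = 6,
                              depth_range = c(2000L, 5000L),
                              lowdepth_range = c(20L, 60L),
                              n_lowdepth = round(0.05 * n_cells),
                              seed = 1L) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8, length(proportions) == k_clusters,
            k_clusters * marker_genes <= n_genes, n_lowdepth < n_cells)
  with_seed(seed, {
    sizes <- diff(c(0L, round(cumsum(proportions) * n_cells)))
    labels <- sample(rep(seq_len(k_clusters), times = sizes))
    profiles <- matrix(1, k_clusters, n_genes)
    for (k in seq_len(k_clusters)) {
      block <- ((k - 1L) * marker_genes + 1L):(k * marker_genes)
      profiles[k, block] <- marker_weight
    }
    profiles <- profiles / rowSums(profiles)
    depths <- sample(depth_range[1]:depth_range[2], n_cells, replace = TRUE)
    low_idx <- sort(sample(n_cells, n_lowdepth))
    depths[low_idx] <- sample(lowdepth_range[1]:lowdepth_range[2],
                              n_lowdepth, replace = TRUE)
    m <- t(vapply(seq_len(n_cells), function(i) {
      as.integer(stats::rmultinom(1, depths[i], profiles[labels[i], ]))
    }, integer(n_genes)))
    rownames(m) <- sprintf("cell%03d", seq_len(n_cells))
    colnames(m) <- sprintf("gene%03d", seq_len(n_genes))
    list(matrix = list(counts = m),
         labels = stats::setNames(labels, rownames(m)),
         lowdepth_cells = rownames(m)[low_idx])
  })
}

#' Write a labelled table or count matrix to CSV
#'
#' @param x A data frame (written without row names) or a count-matrix
#'   payload (\code{list(counts = ...)}, written with cell identifiers in
#'   the first column).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fixture_csv <- function(x, path) {
  if (is.data.frame(x)) {
    utils::write.csv(x, path, row.names = FALSE)
  } else if (is.list(x) && !is.null(x$counts)) {
    utils::write.csv(as.data.frame(x$counts), path, row.names = TRUE)
  } else {
    stop("unsupported fixture type", call. = FALSE)
  }
  invisible(path)
}
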