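#' SC3-style consensus clustering configuration
#'
#' The clusterer follows the SC3 recipe: several cell-cell distance matrices,
#' several spectral transformations, k-means on each embedding, and a
#' complete-linkage cut of the averaged co-clustering (consensus) matrix.
#'
#' @param k Number of clusters to produce.
#' @param metrics Subset of `c("euclidean", "pearson", "spearman")`.
#'   Correlation distances are 1 - correlation.
#' @param transforms Subset of `c("pca", "laplacian")`.
#' @param d_range Integer vector of embedding dimensionalities. `NULL`
#'   (default) selects dimensions spanning 4--7% of the number of cells at
#'   clustering time (the SC3 convention), at least 2, capped at n - 1, and
#'   thinned to at most `d_max_points` values to bound runtime.
#' @param kmeans_restarts Number of random k-means starts per embedding.
#' @param kmeans_iter_max Maximum k-means iterations.
#' @param d_max_points Maximum number of `d` values when `d_range` is
#'   derived automatically.
#' @param seed Seed controlling every k-means run.
#' @return An `sc3_config` list.
#' @export
sc3_config <- function(k, metrics = c("euclidean", "pearson", "spearman"),
                       transforms = c("pca", "laplacian"),
                       d_range = NULL, kmeans_restarts = 10,
                       kmeans_iter_max = 100, d_max_points = 4, seed = 0) {
  metrics <- match.arg(metrics, c("euclidean", "pearson", "spearman"),
                       several.ok = TRUE)
  transforms <- match.arg(transforms, c("pca", "laplacian"),
                          several.ok = TRUE)
  stopifnot(k >= 1, kmeans_restarts >= 1, d_max_points >= 1)
  if (!is.null(d_range)) stopifnot(all(d_range >= 1))
  structure(list(k = as.integer(k), metrics = metrics,
                 transforms = transforms, d_range = d_range,
                 kmeans_restarts = as.integer(kmeans_restarts),
                 kmeans_iter_max = as.integer(kmeans_iter_max),
                 d_max_points = as.integer(d_max_points),
                 seed = as.integer(seed)),
            class = "sc3_config")
}

#' Default embedding dimensions for n cells
#'
#' 4--7% of n per the SC3 convention, clipped to [2, n - 1] and thinned to
#' at most `max_points` values.
#'
#' @param n Number of cells.
#' @param max_points Maximum number of values returned.
#' @return An integer vector of embedding dimensions.
#' @export
default_d_range <- function(n, max_points = 4) {
  lo <- max(2L, floor(0.04 * n + 1e-9))
  hi <- max(lo, ceiling(0.07 * n - 1e-9))
  dd <- unique(pmin(lo:hi, n - 1L))
  dd <- dd[dd >= 1L]
  if (length(dd) > max_points)
    dd <- unique(round(seq(dd[1L], dd[length(dd)], length.out = max_points)))
  dd
}

#' Cell-cell distance matrices
#'
#' @param x An [expr_matrix] or matrix (genes x cells) with at least 2 cells.
#' @param metrics Subset of `c("euclidean", "pearson", "spearman")`.
#' @return Named list of symmetric n x n distance matrices with zero
#'   diagonal; correlation distances are 1 - correlation, and pairs
#'   involving a constant cell profile get correlation 0 (distance 1).
#' @export
distance_matrices <- function(x, metrics = c("euclidean", "pearson",
                                             "spearman")) {
  v <- if (inherits(x, "expr_matrix")) unclass(x) else as.matrix(x)
  if (ncol(v) < 2L) stop("need at least 2 cells", call. = FALSE)
  metrics <- match.arg(metrics, c("euclidean", "pearson", "spearman"),
                       several.ok = TRUE)
  out <- list()
  for (m in metrics) {
    d <- switch(m,
      euclidean = as.matrix(stats::dist(t(v), method = "euclidean")),
      pearson = {
        cc <- suppressWarnings(stats::cor(v, method = "pearson"))
        cc[!is.finite(cc)] <- 0     # constant profiles: correlation -> 0
        1 - cc
      },
      spearman = {
        cc <- suppressWarnings(stats::cor(v, method = "spearman"))
        cc[!is.finite(cc)] <- 0
        1 - cc
      })
    diag(d) <- 0
    d <- (d + t(d)) / 2
    dimnames(d) <- list(colnames(v), colnames(v))
    out[[m]] <- d
  }
  out
}

#' Spectral embedding of a distance matrix
#'
#' `pca`: the first `d` principal components of the (column-centered)
#' distance matrix. `laplacian`: the eigenvectors belonging to the `d`
#' smallest eigenvalues of the symmetric normalized graph Laplacian of the
#' similarity `exp(-D / max(D))`.
#'
#' @param d_mat Symmetric n x n distance matrix.
#' @param transform `"pca"` or `"laplacian"`.
#' @param d Embedding dimension, `1 <= d < n`.
#' @return An n x d embedding matrix (cells in rows).
#' @export
transform_distance <- function(d_mat, transform = c("pca", "laplacian"), d) {
  transform <- match.arg(transform)
  d_mat <- as.matrix(d_mat)
  n <- nrow(d_mat)
  if (d >= n) stop("embedding dimension d must be < n", call. = FALSE)
  if (transform == "pca") {
    centered <- scale(d_mat, center = TRUE, scale = FALSE)
    sv <- svd(centered, nu = 0, nv = d)
    emb <- centered %*% sv$v[, seq_len(d), drop = FALSE]
  } else {
    mx <- max(d_mat)
    a <- if (mx > 0) exp(-d_mat / mx) else matrix(1, n, n)
    deg <- rowSums(a)
    if (any(deg <= 0))
      stop("degenerate eigenproblem: isolated node in similarity graph",
           call. = FALSE)
    inv_sqrt <- 1 / sqrt(deg)
    lap <- diag(n) - (inv_sqrt * a) * rep(inv_sqrt, each = n)
    eig <- eigen(lap, symmetric = TRUE)
    idx <- order(eig$values)[seq_len(d)]     # smallest eigenvalues
    emb <- eig$vectors[, idx, drop = FALSE]
  }
  rownames(emb) <- rownames(d_mat)
  emb
}

# All (metric, transform, d) k-means label matrices for the consensus.
sc3_partition_labels <- function(x, cfg) {
  v <- if (inherits(x, "expr_matrix")) unclass(x) else as.matrix(x)
  n <- ncol(v)
  if (cfg$k > n) stop("k exceeds the number of cells", call. = FALSE)
  d_range <- cfg$d_range %||% default_d_range(n, cfg$d_max_points)
  d_range <- unique(pmin(as.integer(d_range), n - 1L))
  dists <- distance_matrices(v, cfg$metrics)
  labels <- list()
  run <- 0L
  for (m in cfg$metrics) {
    for (tr in cfg$transforms) {
      for (d in d_range) {
        run <- run + 1L
        emb <- transform_distance(dists[[m]], tr, d)
        # individual runs are consensus votes; Lloyd non-convergence
        # warnings on tie-heavy embeddings are expected and benign
        km <- withr::with_seed(cfg$seed + run, {
          suppressWarnings(stats::kmeans(emb, centers = cfg$k,
                                         nstart = cfg$kmeans_restarts,
                                         iter.max = cfg$kmeans_iter_max))
        })
        labels[[run]] <- km$cluster
      }
    }
  }
  labels
}

#' Consensus matrix from k-means partitions
#'
#' @param label_list List of integer label vectors of equal length n.
#' @return Symmetric n x n matrix in [0, 1] with unit diagonal; entry (i, j)
#'   is the fraction of partitions placing cells i and j together.
#' @export
consensus_matrix <- function(label_list) {
  n <- length(label_list[[1L]])
  cons <- matrix(0, n, n)
  for (lab in label_list) {
    cons <- cons + outer(lab, lab, "==")
  }
  cons / length(label_list)
}

#' SC3-style consensus clustering
#'
#' Runs seeded k-means on every (metric, transform, d) embedding, averages
#' the binary co-clustering matrices into a consensus matrix, and cuts a
#' complete-linkage hierarchical clustering of 1 - consensus at k clusters.
#'
#' @param x An [expr_matrix] or matrix (genes x cells).
#' @param cfg An [sc3_config].
#' @param return_consensus If `TRUE`, attach the consensus matrix as
#'   attribute `"consensus"` to the result.
#' @return Integer labels in \{0..k-1\}, one per cell.
#' @export
consensus_cluster <- function(x, cfg, return_consensus = FALSE) {
  labels <- sc3_partition_labels(x, cfg)
  cons <- consensus_matrix(labels)
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "complete")
  out <- stats::cutree(hc, k = cfg$k) - 1L
  v <- if (inherits(x, "expr_matrix")) unclass(x) else as.matrix(x)
  names(out) <- colnames(v)
  if (return_consensus) attr(out, "consensus") <- cons
  out
}
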