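#' NMF configuration
#'
#' Settings for the elastic-net regularized non-negative matrix factorization
#' used to learn the gene-by-cluster dictionary from the source dataset.
#'
#' The factorization minimizes
#' \deqn{\tfrac12\|X - HW\|_F^2
#'       + \alpha\lambda(\|vec(H)\|_1 + \|vec(W)\|_1)
#'       + \tfrac{\alpha}{2}(1-\lambda)(\|H\|_F^2 + \|W\|_F^2)}
#' over nonnegative H (genes x k) and W (k x cells).
#'
#' @param k Number of clusters / dictionary atoms.
#' @param alpha Elastic-net penalty multiplier (alpha >= 0).
#' @param lam Elastic-net mixing parameter in [0, 1]; 1 is pure L1, 0 pure L2.
#' @param max_iter Maximum number of alternating update sweeps.
#' @param tol Relative objective-change convergence threshold.
#' @param seed Seed for the randomized initialization used when no labels
#'   are supplied.
#' @return An `nmf_config` list.
#' @export
nmf_config <- function(k, alpha = 1.0, lam = 0.5, max_iter = 500,
                       tol = 1e-5, seed = 0) {
  stopifnot(k >= 1, alpha >= 0, lam >= 0, lam <= 1, max_iter >= 1, tol > 0)
  structure(list(k = as.integer(k), alpha = alpha, lam = lam,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "nmf_config")
}

#' One-hot encoding of cluster labels
#'
#' Builds the k x n indicator matrix with entry (j, i) = 1 iff cell i carries
#' label j. Used as the initial loading matrix when source labels are known.
#'
#' @param y Integer labels in \{0, ..., k-1\}.
#' @param k Number of clusters.
#' @return A k x n 0/1 matrix; every column sums to 1.
#' @export
one_hot_init <- function(y, k) {
  y <- as.integer(y)
  if (any(y < 0L) || any(y >= k))
    stop(sprintf("labels must lie in {0..%d}", k - 1L), call. = FALSE)
  w <- matrix(0, nrow = k, ncol = length(y))
  w[cbind(y + 1L, seq_along(y))] <- 1
  w
}

# Evaluate the elastic-net NMF objective.
nmf_objective <- function(x, h, w, alpha, lam) {
  0.5 * sum((x - h %*% w)^2) +
    alpha * lam * (sum(abs(h)) + sum(abs(w))) +
    0.5 * alpha * (1 - lam) * (sum(h^2) + sum(w^2))
}

# One HALS sweep over the columns of `a` in X ~ a b (a: m x k, b: k x n),
# minimizing 0.5||X - ab||^2 + l1*sum(a) + 0.5*l2*sum(a^2) under a >= 0.
# Each column update solves its subproblem exactly, so the objective never
# increases. xb = X t(b) (m x k), bb = b t(b) (k x k) are precomputed.
hals_update <- function(a, xb, bb, l1, l2) {
  k <- ncol(a)
  for (j in seq_len(k)) {
    denom <- bb[j, j] + l2
    if (denom <= 0) { a[, j] <- 0; next }
    grad <- xb[, j] - a %*% bb[, j] + a[, j] * bb[j, j]
    a[, j] <- pmax(0, (grad - l1) / denom)
  }
  a
}

#' Learn a dictionary from the source dataset by elastic-net NMF
#'
#' Factorizes the nonnegative source matrix X (genes x cells, typically
#' log-scale expression) as X ~ H W with H the genes x k dictionary and W
#' the k x cells loading matrix, by exact coordinate updates (HALS) with
#' the elastic-net terms folded in.
#'
#' When source labels are given, W is the one-hot encoding of the labels
#' and, by default, stays fixed while only the dictionary H is fit — the
#' problem is then convex and the global optimum is found regardless of
#' initialization, and the dictionary atoms remain anchored to the labeled
#' clusters (regularized cluster centroids). Setting `update_w = TRUE`
#' instead treats the one-hot encoding as a starting point and alternates
#' updates of both factors (a non-convex local search that can drift away
#' from the label structure). Without labels both factors start from a
#' seeded random nonnegative initialization and are always alternated.
#'
#' @param x An [expr_matrix] or nonnegative matrix (genes x cells).
#' @param y Optional integer labels in \{0..k-1\}, one per cell.
#' @param cfg An [nmf_config].
#' @param update_w When labels are given: alternate updates of W as well
#'   (default `FALSE`, the convex label-anchored fit). Ignored without
#'   labels.
#' @return A `factor_pair` list: `H`, `W`, `objective_trace` (the objective
#'   after each sweep, non-increasing), `iterations`, `converged`.
#' @export
fit_source_nmf <- function(x, y = NULL, cfg, update_w = is.null(y)) {
  v <- if (inherits(x, "expr_matrix")) unclass(x) else as.matrix(x)
  attr(v, "unit") <- NULL
  if (any(v < 0)) stop("NMF requires a nonnegative matrix", call. = FALSE)
  k <- cfg$k
  g <- nrow(v); n <- ncol(v)
  if (!is.null(y)) {
    if (length(y) != n)
      stop("length(y) must equal the number of cells", call. = FALSE)
    w <- one_hot_init(y, k)
    sizes <- pmax(1, rowSums(w))
    h <- (v %*% t(w)) / rep(sizes, each = g)   # cluster centroids
  } else {
    update_w <- TRUE
    withr::with_seed(cfg$seed, {
      scale0 <- sqrt(mean(v) / k)
      h <- matrix(stats::runif(g * k, 0, 2 * scale0), g, k)
      w <- matrix(stats::runif(k * n, 0, 2 * scale0), k, n)
    })
  }
  l1 <- cfg$alpha * cfg$lam
  l2 <- cfg$alpha * (1 - cfg$lam)
  trace <- numeric(0)
  obj <- nmf_objective(v, h, w, cfg$alpha, cfg$lam)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(cfg$max_iter)) {
    h <- hals_update(h, v %*% t(w), w %*% t(w), l1, l2)
    if (update_w) {
      wt <- hals_update(t(w), t(v) %*% h, t(h) %*% h, l1, l2)
      w <- t(wt)
    }
    new_obj <- nmf_objective(v, h, w, cfg$alpha, cfg$lam)
    trace <- c(trace, new_obj)
    if (is.finite(obj) && obj > 0 && abs(obj - new_obj) / obj < cfg$tol) {
      converged <- TRUE
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  if (!converged)
    warning(sprintf("NMF did not converge in %d iterations (objective %.6g)",
                    cfg$max_iter, obj), call. = FALSE)
  rownames(h) <- rownames(v)
  structure(list(H = h, W = w, objective_trace = trace,
                 iterations = iter, converged = converged),
            class = "factor_pair")
}

#' Cluster labels by plain NMF
#'
#' When no trustworthy source labels exist, labels are generated by running
#' the factorization without label initialization and assigning each cell to
#' the row of its column-wise maximum in W (ties to the lowest row index).
#'
#' @inheritParams fit_source_nmf
#' @return Integer labels in \{0..k-1\}, one per cell.
#' @export
nmf_cluster_labels <- function(x, cfg) {
  fit <- fit_source_nmf(x, y = NULL, cfg = cfg)
  apply(fit$W, 2L, which.max) - 1L
}

#' Transfer the source dictionary to a target dataset
#'
#' Solves, per target cell, the nonnegative least-squares problem
#' \deqn{W_{trg} = argmin_{W \ge 0} \tfrac12 \|X_{trg} - H_{src} W\|_F^2}
#' by exact cyclic coordinate descent. The gene rows of the target must
#' align with the dictionary rows.
#'
#' @param x_trg Target [expr_matrix] or matrix (genes x cells).
#' @param h_src Dictionary (genes x k) from [fit_source_nmf()].
#' @param tol Convergence threshold on the largest coordinate update.
#' @param max_iter Maximum sweeps per column.
#' @return The nonnegative k x cells loading matrix.
#' @export
transfer_weights <- function(x_trg, h_src, tol = 1e-10, max_iter = 1000) {
  v <- if (inherits(x_trg, "expr_matrix")) unclass(x_trg) else as.matrix(x_trg)
  h <- as.matrix(h_src)
  if (nrow(v) != nrow(h))
    stop("gene dimension mismatch between target and dictionary",
         call. = FALSE)
  k <- ncol(h)
  gram <- crossprod(h)                # k x k
  b <- crossprod(h, v)                # k x n
  w <- matrix(0, k, ncol(v))
  for (i in seq_len(ncol(v))) {
    wi <- w[, i]
    bi <- b[, i]
    for (sweep in seq_len(max_iter)) {
      delta <- 0
      for (l in seq_len(k)) {
        if (gram[l, l] <= 0) next
        new_val <- max(0, wi[l] + (bi[l] - sum(gram[l, ] * wi)) / gram[l, l])
        delta <- max(delta, abs(new_val - wi[l]))
        wi[l] <- new_val
      }
      if (delta < tol) break
    }
    w[, i] <- wi
  }
  w
}

#' Binarize a loading matrix into hard assignments
#'
#' Returns the 0/1 matrix with a single 1 per column, at the row of the
#' column-wise maximum (ties broken to the lowest row index).
#'
#' @param w A k x cells matrix with at least one row.
#' @return A 0/1 matrix of the same shape; every column sums to 1.
#' @export
binarize_assignments <- function(w) {
  w <- as.matrix(w)
  if (nrow(w) < 1L) stop("W must have at least one row", call. = FALSE)
  out <- matrix(0, nrow(w), ncol(w))
  out[cbind(apply(w, 2L, which.max), seq_len(ncol(w)))] <- 1
  out
}
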