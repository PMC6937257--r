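#' Transfer-learning configuration
#'
#' @param theta_grid Candidate mixture weights, unique values in [0, 1].
#' @param nmf An [nmf_config] for the source dictionary.
#' @param sc3 An [sc3_config] for clustering the mixed target; its `k` may
#'   differ from the dictionary `k` (the dictionary follows the source label
#'   count, the clusterer the number of clusters sought in the target).
#' @param clusterer Clustering function `(matrix, sc3_config) -> labels`;
#'   defaults to [consensus_cluster()].
#' @return A `transfer_config` list.
#' @export
transfer_config <- function(theta_grid = seq(0, 1, by = 0.1), nmf, sc3,
                            clusterer = consensus_cluster) {
  if (length(theta_grid) == 0L)
    stop("theta grid must be non-empty", call. = FALSE)
  if (anyDuplicated(theta_grid) || any(theta_grid < 0) || any(theta_grid > 1))
    stop("theta grid values must be unique and within [0, 1]", call. = FALSE)
  stopifnot(inherits(nmf, "nmf_config"), inherits(sc3, "sc3_config"))
  structure(list(theta_grid = sort(theta_grid), nmf = nmf, sc3 = sc3,
                 clusterer = clusterer),
            class = "transfer_config")
}

#' Convex mixture of reconstruction and original target
#'
#' \deqn{X^{new}_{trg} = \theta H_{src} W' + (1 - \theta) X_{trg}}
#'
#' At theta = 0 the target is returned unchanged; at theta = 1 it is fully
#' replaced by the dictionary reconstruction of its hard assignments.
#'
#' @param x_trg Target matrix (genes x cells), or [expr_matrix].
#' @param h_src Dictionary (genes x k).
#' @param w_prime 0/1 assignment matrix (k x cells) from
#'   [binarize_assignments()].
#' @param theta Mixture weight in [0, 1].
#' @return The mixed matrix, same shape and dimnames as `x_trg`.
#' @export
mix_target <- function(x_trg, h_src, w_prime, theta) {
  if (theta < 0 || theta > 1)
    stop("theta must lie in [0, 1]", call. = FALSE)
  v <- if (inherits(x_trg, "expr_matrix")) unclass(x_trg) else as.matrix(x_trg)
  attr(v, "unit") <- NULL
  class(v) <- "matrix"
  if (theta == 0) return(v)
  recon <- as.matrix(h_src) %*% as.matrix(w_prime)
  if (!all(dim(recon) == dim(v)))
    stop("dimension mismatch between reconstruction and target",
         call. = FALSE)
  out <- theta * recon + (1 - theta) * v
  dimnames(out) <- dimnames(v)
  out
}

#' Kernel target alignment
#'
#' Normalized Frobenius inner product of two kernel matrices,
#' \eqn{\langle K_1,K_2\rangle_F / \sqrt{\langle K_1,K_1\rangle_F
#' \langle K_2,K_2\rangle_F}}; lies in [0, 1] for PSD inputs.
#'
#' @param k1,k2 Symmetric PSD n x n matrices.
#' @return The alignment score.
#' @export
kta_score <- function(k1, k2) {
  k1 <- as.matrix(k1); k2 <- as.matrix(k2)
  if (!all(dim(k1) == dim(k2)))
    stop("kernels must have identical dimensions", call. = FALSE)
  n1 <- sum(k1 * k1); n2 <- sum(k2 * k2)
  if (n1 == 0 || n2 == 0)
    stop("kernel with zero Frobenius norm", call. = FALSE)
  sum(k1 * k2) / sqrt(n1 * n2)
}

# Linear kernel over cells.
linear_kernel <- function(x) {
  v <- if (inherits(x, "expr_matrix")) unclass(x) else as.matrix(x)
  crossprod(v)
}

# Double-center a kernel matrix (projects out the constant component).
center_kernel <- function(k, center = TRUE) {
  if (!center) return(k)
  n <- nrow(k)
  rm <- rowMeans(k)
  k - outer(rm, rep(1, n)) - outer(rep(1, n), colMeans(k)) + mean(k)
}

# Kernel of a hard labeling: L^T L for one-hot L, i.e. 1 iff same label.
label_kernel <- function(y) {
  outer(y, y, "==") * 1
}

#' Select the mixture parameter by kernel target alignment
#'
#' For every theta on the grid the mixed target is built and clustered, and
#' the predicted labeling is scored by kernel target alignment. The theta
#' with the best score wins; ties go to the smallest theta. A clusterer
#' failure at one theta drops that grid point with a warning.
#'
#' By default the label kernel is aligned with the centered linear kernel
#' of the *original* target data: the selected theta is the one whose
#' induced labeling best explains the geometry the target actually has.
#' Scoring against the mixed data itself (`score_on = "mixed"`) is
#' available but degenerate at high theta — the reconstruction
#' \eqn{H W'} has one distinct column per dictionary atom, the clusterer
#' reproduces it exactly, and the alignment becomes self-fulfilling, so
#' theta = 1 always wins and a dissimilar source can never be rejected.
#'
#' @param x_trg Target matrix (genes x cells, log scale).
#' @param h_src Dictionary (genes x k).
#' @param w_prime 0/1 assignment matrix (k x cells).
#' @param cfg A [transfer_config].
#' @param center_kernels Center both kernels before scoring (default
#'   `TRUE`; uncentered alignment is dominated by the mean component of
#'   nonnegative expression kernels).
#' @param score_on `"target"` (default) aligns labels with the original
#'   target kernel; `"mixed"` with the kernel of the mixed data.
#' @return List: `theta_star`, `x_new` (mixed matrix at `theta_star`),
#'   `labels` (its clustering), `scores` (named numeric, one per surviving
#'   grid point).
#' @export
select_theta <- function(x_trg, h_src, w_prime, cfg, center_kernels = TRUE,
                         score_on = c("target", "mixed")) {
  score_on <- match.arg(score_on)
  scores <- stats::setNames(rep(NA_real_, length(cfg$theta_grid)),
                            format(cfg$theta_grid))
  results <- vector("list", length(cfg$theta_grid))
  k_ref <- if (score_on == "target")
    center_kernel(linear_kernel(x_trg), center_kernels)
  for (i in seq_along(cfg$theta_grid)) {
    theta <- cfg$theta_grid[i]
    x_new <- mix_target(x_trg, h_src, w_prime, theta)
    labels <- tryCatch(cfg$clusterer(x_new, cfg$sc3), error = function(e) e)
    if (inherits(labels, "error")) {
      warning(sprintf("clusterer failed at theta = %g: %s",
                      theta, conditionMessage(labels)), call. = FALSE)
      next
    }
    k1 <- if (score_on == "target") k_ref
          else center_kernel(linear_kernel(x_new), center_kernels)
    scores[i] <- kta_score(k1, center_kernel(label_kernel(labels),
                                             center_kernels))
    results[[i]] <- list(x_new = x_new, labels = labels)
  }
  if (all(is.na(scores)))
    stop("clustering failed at every theta on the grid", call. = FALSE)
  best <- which.max(scores)   # ties -> first (grid sorted ascending)
  list(theta_star = cfg$theta_grid[best],
       x_new = results[[best]]$x_new,
       labels = results[[best]]$labels,
       scores = scores[!is.na(scores)])
}

#' Transfer-learning clustering (TransferCluster)
#'
#' The full method: learn an elastic-net NMF dictionary on the labeled
#' source, project the target onto it by nonnegative least squares, binarize
#' the loadings into hard assignments, and cluster the convex mixture of the
#' dictionary reconstruction and the original target, with the mixture
#' weight chosen by kernel target alignment. If no source labels are given,
#' they are first generated by [nmf_cluster_labels()] and used as if real.
#'
#' Source and target must already share an identical, identically ordered
#' gene space (see [intersect_genes()]).
#'
#' @param x_src Source matrix (genes x cells, log scale).
#' @param y_src Optional integer source labels in \{0..k-1\}.
#' @param x_trg Target matrix over the same genes.
#' @param cfg A [transfer_config].
#' @param center_kernels,score_on Passed to [select_theta()].
#' @return List: `labels` (target clustering), `theta_star`, `scores`
#'   (KTA per theta), `fit` (source `factor_pair`), `w_trg`, `x_new`.
#' @export
transfer_cluster <- function(x_src, y_src = NULL, x_trg, cfg,
                             center_kernels = TRUE,
                             score_on = c("target", "mixed")) {
  vs <- if (inherits(x_src, "expr_matrix")) unclass(x_src) else as.matrix(x_src)
  vt <- if (inherits(x_trg, "expr_matrix")) unclass(x_trg) else as.matrix(x_trg)
  if (nrow(vs) != nrow(vt))
    stop("source and target gene spaces differ; run intersect_genes() first",
         call. = FALSE)
  if (is.null(y_src)) y_src <- nmf_cluster_labels(vs, cfg$nmf)
  fit <- fit_source_nmf(vs, y_src, cfg$nmf)
  w_trg <- transfer_weights(vt, fit$H)
  w_prime <- binarize_assignments(w_trg)
  sel <- select_theta(vt, fit$H, w_prime, cfg, center_kernels, score_on)
  list(labels = sel$labels, theta_star = sel$theta_star,
       scores = sel$scores, fit = fit, w_trg = w_trg, x_new = sel$x_new)
}
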