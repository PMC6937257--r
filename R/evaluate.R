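#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same cells,
#' computed from the contingency table:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{M - E}}
#' with \eqn{E = \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2} / \binom{n}{2}}
#' and \eqn{M = \frac12(\sum_i\binom{a_i}{2} + \sum_j\binom{b_j}{2})}.
#'
#' @param a,b Label vectors of equal length (>= 2). Label names are
#'   irrelevant; only the induced partitions matter.
#' @return The ARI, at most 1; 1 iff the partitions coincide.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors must have equal length", call. = FALSE)
  if (length(a) < 2L)
    stop("need at least 2 observations", call. = FALSE)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  e <- sum_a * sum_b / choose(n, 2)
  m <- (sum_a + sum_b) / 2
  if (m == e) return(1)   # both partitions trivial (all-singletons/all-one)
  (sum_ij - e) / (m - e)
}

#' TargetCluster baseline
#'
#' SC3-style consensus clustering of the target dataset alone.
#'
#' @param x_trg Target matrix (genes x cells, log scale).
#' @param cfg An [sc3_config].
#' @return Integer labels in \{0..k-1\}.
#' @export
target_cluster <- function(x_trg, cfg) {
  consensus_cluster(x_trg, cfg)
}

#' ConcatenateCluster baseline
#'
#' Clusters the column-concatenation of source and target and returns the
#' labels of the target cells only (performance is always scored on the
#' target).
#'
#' @param x_src,x_trg Matrices over identical, identically ordered genes.
#' @param cfg An [sc3_config].
#' @return Integer labels for the target cells.
#' @export
concatenate_cluster <- function(x_src, x_trg, cfg) {
  vs <- if (inherits(x_src, "expr_matrix")) unclass(x_src) else as.matrix(x_src)
  vt <- if (inherits(x_trg, "expr_matrix")) unclass(x_trg) else as.matrix(x_trg)
  if (ncol(vs) == 0L) return(consensus_cluster(vt, cfg))
  if (nrow(vs) != nrow(vt))
    stop("source and target gene spaces differ", call. = FALSE)
  combined <- cbind(vs, vt)
  colnames(combined) <- make.unique(c(colnames(vs), colnames(vt)))
  labels <- consensus_cluster(combined, cfg)
  out <- labels[ncol(vs) + seq_len(ncol(vt))]
  names(out) <- colnames(vt)
  out
}

# Map arbitrary integer labels to contiguous 0..k-1 (order-preserving).
relabel_contiguous <- function(y) {
  out <- match(y, sort(unique(y))) - 1L
  names(out) <- names(y)
  out
}

# Per-repetition seed substream (kept well below 2^31).
rep_seed <- function(seed, rep, slot = 0L) {
  (as.integer(seed) %% 100000L) * 20011L + rep * 131L + slot
}

#' Run the simulation study
#'
#' For each repetition and overlap mode: generate a dataset, split it into
#' source and target, pre-process each side separately (cell filter, gene
#' filter, log transform), restrict both to their shared genes, downsample
#' the target to each requested size, run each method, and score the ARI of
#' the predicted target labels against the simulated ground truth. Means
#' and normal-approximation 95% confidence intervals are aggregated per
#' (method, mode, target size).
#'
#' With the default filter (`x_expression = 0`, `x_cells = 94`) the gene
#' filter drops the genes detected in essentially every cell and keeps the
#' sparse low-expression genes, which is what makes the simulated
#' clustering problem non-trivial.
#'
#' @param sim A [sim_config]; its `seed` is superseded by per-repetition
#'   substreams of `seed`.
#' @param modes Overlap regimes to run (subset of
#'   `c("complete", "incomplete", "none")`).
#' @param methods Subset of
#'   `c("TargetCluster", "ConcatenateCluster", "TransferCluster")`.
#' @param target_sizes Target sizes; defaults to `sim$target_sizes`.
#' @param n_reps Number of repetitions.
#' @param seed Master seed.
#' @param theta_grid Mixture grid for TransferCluster.
#' @param filter_cfg A [filter_config] applied to source and target
#'   separately before clustering; `NULL` (default) uses
#'   `x_genes = 0.2 * n_genes`, `x_expression = 0`, `x_cells = 94`.
#' @param nmf_args,sc3_args Extra arguments merged into the per-run
#'   [nmf_config()] / [sc3_config()] (e.g. `alpha`, `kmeans_restarts`).
#' @return An `experiment_result` list: `results` (one row per repetition,
#'   mode, method and size, with the ARI and, for TransferCluster, the
#'   selected theta), `summary` (mean ARI and 95% CI half-width), and
#'   `failures` (count of excluded repetitions).
#' @export
run_simulation_study <- function(sim = sim_config(),
                                 modes = "complete",
                                 methods = c("TargetCluster",
                                             "ConcatenateCluster",
                                             "TransferCluster"),
                                 target_sizes = NULL,
                                 n_reps = 10, seed = 0,
                                 theta_grid = seq(0, 1, by = 0.25),
                                 filter_cfg = NULL,
                                 nmf_args = list(), sc3_args = list()) {
  stopifnot(n_reps >= 1)
  modes <- match.arg(modes, c("complete", "incomplete", "none"),
                     several.ok = TRUE)
  methods <- match.arg(methods, c("TargetCluster", "ConcatenateCluster",
                                  "TransferCluster"), several.ok = TRUE)
  target_sizes <- target_sizes %||% sim$target_sizes
  filter_cfg <- filter_cfg %||%
    filter_config(x_genes = max(1, round(0.2 * sim$n_genes)),
                  x_expression = 0, x_cells = 94)
  rows <- list()
  failures <- 0L
  for (r in seq_len(n_reps)) {
    for (mode in modes) {
      res <- tryCatch(
        run_one_rep(sim, mode, methods, target_sizes, seed, r, theta_grid,
                    filter_cfg, nmf_args, sc3_args),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- failures + 1L
        warning(sprintf("repetition %d (%s) failed: %s", r, mode,
                        conditionMessage(res)), call. = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- res
    }
  }
  results <- do.call(rbind, rows)
  summary <- aggregate_results(results)
  structure(list(results = results, summary = summary, failures = failures),
            class = "experiment_result")
}

run_one_rep <- function(sim, mode, methods, target_sizes, seed, r,
                        theta_grid, filter_cfg, nmf_args, sc3_args) {
  cfg <- sim
  cfg$seed <- rep_seed(seed, r, 1L)
  d <- generate_dataset(cfg)
  split_sizes <- switch(mode,
    complete = list(n_src = sim$n_src,
                    n_trg = sim$n_cells - sim$n_src),
    incomplete = list(n_src = NULL, n_trg = NULL),
    none = list(n_src = NULL, n_trg = NULL))
  sp <- split_source_target(d, mode, split_sizes$n_src, split_sizes$n_trg,
                            seed = rep_seed(seed, r, 2L))
  pre <- function(ds) {
    x <- gene_filter(cell_filter(ds$X, filter_cfg), filter_cfg)
    list(X = x, y = ds$y[cell_ids(x)])
  }
  ps <- pre(sp$source)
  pt <- pre(sp$target)
  shared <- intersect_genes(ps$X, pt$X)
  x_src <- log_transform(shared$a)
  y_src <- relabel_contiguous(ps$y)
  k_dict <- length(unique(y_src))
  x_trg_full <- log_transform(shared$b)
  rows <- list()
  for (nt in target_sizes) {
    nt_eff <- min(nt, ncol(x_trg_full))
    dt <- downsample(list(X = x_trg_full, y = pt$y,
                          top_node_of = sp$target$top_node_of),
                     nt_eff, seed = rep_seed(seed, r, 3L) + nt)
    truth <- dt$y
    k_clust <- length(unique(truth))
    s3 <- do.call(sc3_config,
                  c(list(k = k_clust, seed = rep_seed(seed, r, 4L) + nt),
                    sc3_args))
    for (method in methods) {
      theta <- NA_real_
      pred <- switch(method,
        TargetCluster = target_cluster(dt$X, s3),
        ConcatenateCluster = concatenate_cluster(x_src, dt$X, s3),
        TransferCluster = {
          nm <- do.call(nmf_config,
                        c(list(k = k_dict, seed = rep_seed(seed, r, 5L)),
                          nmf_args))
          tc <- transfer_cluster(x_src, y_src, dt$X,
                                 transfer_config(theta_grid, nm, s3))
          theta <- tc$theta_star
          tc$labels
        })
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, mode = mode, method = method, n_trg = nt_eff,
        ari = adjusted_rand_index(truth, pred), theta_star = theta,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

aggregate_results <- function(results) {
  if (is.null(results) || nrow(results) == 0L) return(NULL)
  agg <- stats::aggregate(ari ~ method + mode + n_trg, data = results,
                          FUN = function(v) {
                            c(mean = mean(v), n = length(v),
                              sd = stats::sd(v))
                          })
  out <- data.frame(method = agg$method, mode = agg$mode, n_trg = agg$n_trg,
                    mean_ari = agg$ari[, "mean"],
                    n = agg$ari[, "n"],
                    stringsAsFactors = FALSE)
  out$ci95 <- ifelse(out$n >= 2,
                     1.96 * agg$ari[, "sd"] / sqrt(out$n), NA_real_)
  out[order(out$mode, out$n_trg, out$method), ]
}

#' @method print experiment_result
#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: %d rows, %d failures\n",
              if (is.null(x$results)) 0L else nrow(x$results), x$failures))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Cluster-separation criterion
#'
#' A predicate on a predicted labeling used by the robustness protocol:
#' by default, the reference cell groups are "successfully identified" when
#' their majority predicted clusters are pairwise distinct.
#'
#' @param groups Named list of two or more disjoint, non-empty character
#'   vectors of cell ids.
#' @param rule Optional custom predicate `function(labels) -> logical`;
#'   overrides the majority-separation rule.
#' @return A `separation_criterion` object.
#' @export
separation_criterion <- function(groups, rule = NULL) {
  stopifnot(length(groups) >= 2L)
  if (any(lengths(groups) == 0L))
    stop("criterion groups must be non-empty", call. = FALSE)
  all_ids <- unlist(groups)
  if (anyDuplicated(all_ids))
    stop("criterion groups must be disjoint", call. = FALSE)
  structure(list(groups = groups, rule = rule),
            class = "separation_criterion")
}

criterion_met <- function(crit, labels) {
  if (!is.null(crit$rule)) return(isTRUE(crit$rule(labels)))
  majorities <- vapply(crit$groups, function(ids) {
    lab <- labels[ids]
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0L) return(NA_integer_)
    as.integer(names(sort(table(lab), decreasing = TRUE))[1L])
  }, integer(1))
  if (anyNA(majorities)) return(FALSE)
  !anyDuplicated(majorities)
}

#' Robustness counting protocol
#'
#' Re-runs a (non-deterministic) clustering method `n_reps` times with
#' fresh clusterer seeds and counts, for each criterion, how often the
#' predicted labeling satisfies it. A failed repetition counts as
#' non-success for every criterion.
#'
#' @param method A function `function(seed) -> named labels` wrapping the
#'   clustering run (the seed varies per repetition).
#' @param criteria List of [separation_criterion] objects.
#' @param n_reps Number of repetitions (>= 1).
#' @param seed Base seed for the repetition substreams.
#' @return Integer vector of success counts, one per criterion (named when
#'   `criteria` is named), with attribute `"n_reps"`.
#' @export
robustness_count <- function(method, criteria, n_reps, seed = 0) {
  if (n_reps < 1) stop("n_reps must be at least 1", call. = FALSE)
  counts <- stats::setNames(integer(length(criteria)), names(criteria))
  for (r in seq_len(n_reps)) {
    labels <- tryCatch(method(rep_seed(seed, r)), error = function(e) NULL)
    if (is.null(labels)) next
    for (i in seq_along(criteria)) {
      if (criterion_met(criteria[[i]], labels))
        counts[i] <- counts[i] + 1L
    }
  }
  attr(counts, "n_reps") <- as.integer(n_reps)
  counts
}
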