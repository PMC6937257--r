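#' The fixed simulation cluster hierarchy
#'
#' Eight leaf cell clusters derived from five top-level clusters (V--Z).
#' Top nodes V, W and X are themselves leaf clusters (1--3); Y splits into
#' leaves 4--5 and Z into leaves 6--8. Leaf labels are 0-based (leaf j has
#' label j - 1).
#'
#' @return A list with `top_nodes` (character), `leaves` (integer ids 1..8)
#'   and `leaf_top` (named character: top node of each leaf).
#' @export
cluster_tree <- function() {
  list(top_nodes = c("V", "W", "X", "Y", "Z"),
       leaves = 1:8,
       leaf_top = c(`1` = "V", `2` = "W", `3` = "X",
                    `4` = "Y", `5` = "Y",
                    `6` = "Z", `7` = "Z", `8` = "Z"))
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions of the hierarchical scRNA-Seq
#' count simulator: 10 000 genes, 1800 cells of which 1000 form the source,
#' Dirichlet(10) cluster proportions, Gamma(2, 0.1) background gene means,
#' per-node differential expression of a uniform 10--40% of genes with
#' log2 fold changes drawn from Normal(1, 0.5) and random sign, 10%
#' multiplicative Gaussian cell noise, and negative-binomial counts with
#' dispersion 0.1 (variance mu + 0.1 mu^2).
#'
#' @param n_genes,n_cells,n_src Problem sizes.
#' @param target_sizes Downsampled target sizes examined by the harness.
#' @param dirichlet_concentration Concentration of the symmetric Dirichlet
#'   over leaf-cluster proportions.
#' @param gamma_shape,gamma_rate Background gene-mean distribution.
#' @param de_fraction_range Range the per-node DE gene fraction is drawn
#'   from (uniformly).
#' @param lfc_mean,lfc_sd Log2 fold-change distribution for DE genes.
#' @param nb_dispersion Negative-binomial dispersion; 0 gives Poisson
#'   counts.
#' @param cell_noise_sd SD of the multiplicative per-entry Gaussian noise
#'   applied to expression levels before count sampling.
#' @param seed Master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 10000, n_cells = 1800, n_src = 1000,
                       target_sizes = c(10, 50, 100, 200, 400, 600, 800),
                       dirichlet_concentration = 10,
                       gamma_shape = 2, gamma_rate = 0.1,
                       de_fraction_range = c(0.10, 0.40),
                       lfc_mean = 1, lfc_sd = 0.5,
                       nb_dispersion = 0.1, cell_noise_sd = 0.1,
                       seed = 0) {
  stopifnot(n_genes >= 1, n_cells >= 8, n_src >= 1,
            dirichlet_concentration > 0, gamma_shape > 0, gamma_rate > 0,
            length(de_fraction_range) == 2,
            de_fraction_range[1] > 0, de_fraction_range[2] <= 1,
            de_fraction_range[1] <= de_fraction_range[2],
            lfc_sd > 0, nb_dispersion >= 0, cell_noise_sd >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_cells = as.integer(n_cells),
                 n_src = as.integer(n_src),
                 target_sizes = as.integer(target_sizes),
                 dirichlet_concentration = dirichlet_concentration,
                 gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                 de_fraction_range = de_fraction_range,
                 lfc_mean = lfc_mean, lfc_sd = lfc_sd,
                 nb_dispersion = nb_dispersion,
                 cell_noise_sd = cell_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Run `expr` under `seed` when given, else in the current RNG stream.
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Dirichlet draw of leaf-cluster sizes
#'
#' Draws proportions from a symmetric Dirichlet and converts them to
#' integer sizes summing exactly to `n_cells` by largest-remainder
#' rounding, with a minimum of one cell per leaf.
#'
#' @param n_cells Total number of cells.
#' @param n_leaves Number of leaf clusters.
#' @param concentration Dirichlet concentration parameter.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Integer vector of length `n_leaves`, all >= 1, summing to
#'   `n_cells`.
#' @export
sample_cluster_sizes <- function(n_cells, n_leaves,
                                 concentration = 10, seed = NULL) {
  if (n_cells < n_leaves)
    stop("n_cells must be at least n_leaves", call. = FALSE)
  with_opt_seed(seed, {
    gam <- stats::rgamma(n_leaves, shape = concentration, rate = 1)
    p <- gam / sum(gam)
    raw <- p * n_cells
    sizes <- floor(raw)
    short <- n_cells - sum(sizes)
    if (short > 0) {
      extra <- order(raw - sizes, decreasing = TRUE)[seq_len(short)]
      sizes[extra] <- sizes[extra] + 1
    }
    # enforce >= 1 by borrowing from the largest clusters
    while (any(sizes < 1)) {
      i <- which.min(sizes); j <- which.max(sizes)
      sizes[i] <- sizes[i] + 1L; sizes[j] <- sizes[j] - 1L
    }
    as.integer(sizes)
  })
}

# Apply one round of differential expression to a profile: a uniformly
# drawn fraction of genes gets a log2 fold change ~ N(lfc_mean, lfc_sd)
# with random sign.
apply_de <- function(profile, cfg) {
  g <- length(profile)
  frac <- stats::runif(1, cfg$de_fraction_range[1], cfg$de_fraction_range[2])
  idx <- sample.int(g, max(1L, round(frac * g)))
  lfc <- stats::rnorm(length(idx), cfg$lfc_mean, cfg$lfc_sd)
  sgn <- sample(c(-1, 1), length(idx), replace = TRUE)
  profile[idx] <- profile[idx] * 2^(sgn * lfc)
  profile
}

#' Generate a hierarchical scRNA-Seq count dataset
#'
#' Background per-gene mean expression is drawn from a Gamma distribution;
#' each top-level cluster perturbs a random 10--40% of genes by log2 fold
#' changes, and leaves under a multi-leaf top node repeat the process with
#' the parent profile as the new background. Per-cell expression receives
#' multiplicative Gaussian noise, and counts are sampled from a negative
#' binomial with the configured dispersion (Poisson when dispersion is 0).
#'
#' @param cfg A [sim_config].
#' @return A `labeled_dataset` list: `X` (count [expr_matrix]), `y`
#'   (0-based leaf labels per cell), `top_node_of` (character vector:
#'   the top node of each label value, indexed by label + 1).
#' @export
generate_dataset <- function(cfg = sim_config()) {
  tree <- cluster_tree()
  n_leaves <- length(tree$leaves)
  with_opt_seed(cfg$seed, {
    sizes <- sample_cluster_sizes(cfg$n_cells, n_leaves,
                                  cfg$dirichlet_concentration, seed = NULL)
    background <- stats::rgamma(cfg$n_genes, shape = cfg$gamma_shape,
                                rate = cfg$gamma_rate)
    top_profiles <- sapply(tree$top_nodes,
                           function(nd) apply_de(background, cfg))
    leaf_profiles <- matrix(0, cfg$n_genes, n_leaves)
    for (j in seq_len(n_leaves)) {
      top <- tree$leaf_top[[as.character(tree$leaves[j])]]
      parent <- top_profiles[, top]
      multi <- sum(tree$leaf_top == top) > 1L
      leaf_profiles[, j] <- if (multi) apply_de(parent, cfg) else parent
    }
    y <- rep(seq_len(n_leaves) - 1L, times = sizes)
    mu <- leaf_profiles[, y + 1L, drop = FALSE]
    if (cfg$cell_noise_sd > 0) {
      noise <- pmax(0, 1 + stats::rnorm(length(mu), 0, cfg$cell_noise_sd))
      mu <- mu * noise
    }
    counts <- if (cfg$nb_dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    } else {
      stats::rpois(length(mu), lambda = mu)
    }
    counts <- matrix(as.numeric(counts), cfg$n_genes, cfg$n_cells)
    x <- expr_matrix(counts,
                     gene_ids = paste0("gene_", seq_len(cfg$n_genes)),
                     cell_ids = paste0("cell_", seq_len(cfg$n_cells)),
                     unit = "counts")
    names(y) <- cell_ids(x)
    structure(list(X = x, y = y, top_node_of = unname(tree$leaf_top)),
              class = "labeled_dataset")
  })
}

# Subset a labeled dataset to a set of cell indices.
dataset_subset <- function(d, idx) {
  structure(list(X = subset_expr(d$X, cells = idx),
                 y = d$y[idx],
                 top_node_of = d$top_node_of),
            class = "labeled_dataset")
}

#' Split a dataset into source and target under an overlap regime
#'
#' `complete`: cells are randomly partitioned and both sides contain cells
#' from every top node. `incomplete`: three randomly chosen top nodes are
#' shared; of the remaining two, one is exclusive to the source and one to
#' the target. `none`: two randomly chosen top nodes form the target pool
#' and the other three the source pool. No cell ever appears on both sides.
#'
#' @param d A `labeled_dataset` from [generate_dataset()].
#' @param mode `"complete"`, `"incomplete"` or `"none"`.
#' @param n_src,n_trg Requested sizes; `NULL` takes the whole eligible
#'   pool. Requests beyond the eligible pool are errors.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A list with `labeled_dataset` elements `source` and `target`.
#' @export
split_source_target <- function(d, mode = c("complete", "incomplete", "none"),
                                n_src = NULL, n_trg = NULL, seed = NULL) {
  mode <- match.arg(mode)
  n <- ncol(d$X)
  tops <- d$top_node_of[d$y + 1L]
  top_names <- unique(d$top_node_of)
  with_opt_seed(seed, {
    if (mode == "complete") {
      ns <- n_src %||% floor(n / 2)
      nt <- n_trg %||% (n - ns)
      if (ns + nt > n)
        stop("requested sizes exceed available cells", call. = FALSE)
      for (try in 1:100) {
        perm <- sample.int(n)
        src_idx <- perm[seq_len(ns)]
        trg_idx <- perm[ns + seq_len(nt)]
        ok <- all(top_names %in% tops[src_idx]) &&
          all(top_names %in% tops[trg_idx])
        if (ok) break
      }
      if (!ok)
        stop("could not place every top node on both sides", call. = FALSE)
    } else if (mode == "incomplete") {
      shared <- sample(top_names, 3)
      excl <- sample(setdiff(top_names, shared))   # random order
      src_only <- excl[1]; trg_only <- excl[2]
      src_excl <- which(tops == src_only)
      trg_excl <- which(tops == trg_only)
      shared_cells <- sample(which(tops %in% shared))
      ns <- n_src %||% (length(src_excl) + floor(length(shared_cells) / 2))
      nt <- n_trg %||% (n - ns)
      need_src <- max(0L, ns - length(src_excl))
      need_trg <- max(0L, nt - length(trg_excl))
      if (need_src + need_trg > length(shared_cells))
        stop("requested sizes exceed eligible cells", call. = FALSE)
      m <- if (need_src + need_trg > 0)
        round(length(shared_cells) * need_src / (need_src + need_trg))
      else 0L
      m <- min(max(m, need_src), length(shared_cells) - need_trg)
      src_pool <- c(src_excl, shared_cells[seq_len(m)])
      trg_pool <- c(trg_excl, shared_cells[setdiff(seq_along(shared_cells),
                                                   seq_len(m))])
      src_idx <- sample(src_pool, ns)
      trg_idx <- sample(trg_pool, nt)
    } else {   # none
      trg_nodes <- sample(top_names, 2)
      src_nodes <- setdiff(top_names, trg_nodes)
      src_pool <- which(tops %in% src_nodes)
      trg_pool <- which(tops %in% trg_nodes)
      ns <- n_src %||% length(src_pool)
      nt <- n_trg %||% length(trg_pool)
      if (ns > length(src_pool) || nt > length(trg_pool))
        stop("requested sizes exceed eligible cells", call. = FALSE)
      src_idx <- sample(src_pool, ns)
      trg_idx <- sample(trg_pool, nt)
    }
    list(source = dataset_subset(d, sort(src_idx)),
         target = dataset_subset(d, sort(trg_idx)))
  })
}

#' Downsample a labeled dataset
#'
#' Uniform random subset of `n` cells without replacement, labels carried
#' along.
#'
#' @param d A `labeled_dataset`.
#' @param n Number of cells to keep.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return The downsampled `labeled_dataset`.
#' @export
downsample <- function(d, n, seed = NULL) {
  if (n > ncol(d$X))
    stop("cannot downsample beyond the number of cells", call. = FALSE)
  with_opt_seed(seed, dataset_subset(d, sort(sample.int(ncol(d$X), n))))
}

#' @method print labeled_dataset
#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d genes x %d cells, %d clusters\n",
              nrow(x$X), ncol(x$X), length(unique(x$y))))
  invisible(x)
}
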