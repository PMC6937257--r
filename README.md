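# sctransfer

Transfer learning for single-cell RNA-Seq clustering via NMF dictionaries.

## What it does, and for whom

Single-cell RNA-Seq experiments on specific tissues or diseases often
yield small datasets (a few hundred cells) in which rare cell types
cluster unreliably. Large, well-annotated reference atlases of related
tissue usually exist. `sctransfer` is for analysts who want to exploit
such a reference ("source") to stabilize the clustering of a small
unlabeled dataset ("target") — without pooling the two datasets (which
backfires when their cell-type compositions differ) and without
restricting the target to the source's cell types.

The idea: learn what the source's cell types look like, nudge each
target cell toward the source type it resembles, and cluster the nudged
data. How hard to nudge is decided automatically, so an unrelated source
is ignored rather than harmful.

## The method

Given a log-scale source matrix X<sub>src</sub> (g genes × n cells) with
labels y<sup>src</sup> ∈ {0..k−1} and a target X<sub>trg</sub> over the
same genes:

1. **Dictionary** — elastic-net regularized NMF of the source,
   X<sub>src</sub> ≈ H W, minimizing
   ½‖X<sub>src</sub> − HW‖²<sub>F</sub> +
   αλ(‖vec(H)‖₁ + ‖vec(W)‖₁) + (α/2)(1−λ)(‖H‖²<sub>F</sub> + ‖W‖²<sub>F</sub>),
   with W the one-hot encoding of y<sup>src</sup> (held fixed by
   default, making the fit convex; H's columns are shrunken cluster
   centroids). Without labels, NMF clustering of the source generates
   them first.
2. **Transfer** — W<sub>trg</sub> = argmin<sub>W≥0</sub>
   ½‖X<sub>trg</sub> − H W‖²<sub>F</sub> (per-cell nonnegative least
   squares), then W′ keeps a single 1 at each column maximum.
3. **Mixing** — X<sup>new</sup><sub>trg</sub> = θ·H W′ + (1−θ)·X<sub>trg</sub>,
   0 ≤ θ ≤ 1.
4. **Clustering** — SC3-style consensus clustering (k-means over
   Euclidean/Pearson/Spearman distances under PCA and Laplacian
   transforms; complete-linkage cut of the consensus matrix).

θ is chosen from a grid by kernel target alignment: each candidate's
predicted labeling is scored against the centered linear kernel of the
original target data, and the best-aligned θ wins. When source and
target share no cell types, low θ wins and the target is left almost
untouched.

The package also ships the hierarchical negative-binomial count
simulator used for validation (eight leaf clusters under five top-level
clusters; Gamma backgrounds, recursive log2 fold changes, NB dispersion
0.1), the TargetCluster/ConcatenateCluster baselines, and an ARI
evaluation harness with repetition-level confidence intervals.

## Worked example

Simulate a dataset, split it into a 500-cell labeled source and a
400-cell target (complete cell-type overlap), pre-process each side,
downsample the target to 100 cells, and compare transfer clustering with
clustering the target alone:

```r
library(sctransfer)

sim <- sim_config(n_genes = 2000, n_cells = 900, n_src = 500, seed = 7)
d   <- generate_dataset(sim)
sp  <- split_source_target(d, "complete", n_src = 500, n_trg = 400, seed = 8)

fc  <- filter_config(x_genes = 400, x_expression = 0, x_cells = 94)
pre <- function(ds) {
  x <- gene_filter(cell_filter(ds$X, fc), fc)
  list(X = log_transform(x), y = ds$y[cell_ids(x)])
}
src <- pre(sp$source); trg <- pre(sp$target)
shared <- intersect_genes(src$X, trg$X)          # 107 genes survive

trg_small <- downsample(list(X = shared$b, y = trg$y,
                             top_node_of = d$top_node_of), 100, seed = 9)

cfg <- transfer_config(theta_grid = c(0, 0.25, 0.5, 0.75, 1),
                       nmf = nmf_config(k = 8, seed = 1),
                       sc3 = sc3_config(k = length(unique(trg_small$y)),
                                        seed = 2))
res <- transfer_cluster(shared$a, src$y, trg_small$X, cfg)

res$theta_star
#> [1] 0.25
round(res$scores, 4)
#>   0.00   0.25   0.50   0.75   1.00
#> 0.6642 0.6682 0.6682 0.6682 0.6682
adjusted_rand_index(trg_small$y, res$labels)
#> [1] 1
adjusted_rand_index(trg_small$y, target_cluster(trg_small$X, cfg$sc3))
#> [1] 0.9540636
```

The alignment scores identify θ = 0.25 as the best mixture: a modest
pull toward the source centroids fixes the cells that clustering the
100-cell target alone misplaces (ARI 0.954 → 1.000 against the simulated
ground truth).

A command-line wrapper over the same functions is installed at
`inst/cli/sctransfer.R` with subcommands `simulate`, `cluster`,
`transfer`, `evaluate`; each writes its outputs plus a JSON run record.

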