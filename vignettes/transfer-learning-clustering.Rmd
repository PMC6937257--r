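---
title: "Transfer learning for single-cell RNA-Seq clustering: model, design choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer learning for single-cell RNA-Seq clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clustering is the workhorse analysis of single-cell RNA-Seq: cells are
grouped by transcriptional state to define cell types. Small,
tissue- or disease-specific datasets cluster poorly — rare populations are
represented by a handful of cells and the clustering is unstable. Large,
well-annotated reference atlases exist for many tissues. `sctransfer`
implements a transfer-learning approach that uses such a labeled reference
("source") to improve the clustering of a small unlabeled dataset
("target") without forcing the target to contain only source cell types,
and without ever pooling the two datasets into one.

## The method

Let $X_{src} \in \mathbb{R}^{g \times n_{src}}$ be the source expression
matrix (log scale after pre-processing) with labels
$y^{src} \in \{0..k-1\}$, and $X_{trg} \in \mathbb{R}^{g \times n_{trg}}$
the target over the same $g$ genes.

1. **Dictionary learning.** Factorize $X_{src} \approx H W$ with
   nonnegative $H$ ($g \times k$) and $W$ ($k \times n_{src}$),
   minimizing
   $$\tfrac12\|X_{src}-HW\|_F^2
     + \alpha\lambda(\|vec(H)\|_1+\|vec(W)\|_1)
     + \tfrac{\alpha}{2}(1-\lambda)(\|H\|_F^2+\|W\|_F^2).$$
   $W$ is the one-hot encoding of $y^{src}$. By default `sctransfer`
   keeps $W$ fixed and fits only $H$: the problem is then convex, the
   solution is the global optimum independent of initialization, and each
   dictionary atom is an (elastic-net shrunken) centroid of one labeled
   cluster. The alternating variant that also updates $W$ from the
   one-hot starting point is available (`update_w = TRUE`); it lowers the
   objective further but lets $W$ drift toward an unsupervised local
   optimum, weakening the very label anchoring the transfer is meant to
   exploit. When no labels exist, labels are first generated by
   unsupervised NMF clustering of the source (`nmf_cluster_labels()`,
   column-wise argmax of $W$) and used as if they were real.
2. **Transfer.** $W_{trg} = \arg\min_{W \ge 0}
   \tfrac12\|X_{trg} - H W\|_F^2$, solved per target cell by exact cyclic
   coordinate descent. Nonnegativity is imposed for consistency with the
   NMF frame (the unconstrained solution can assign negative cluster
   loadings, which have no interpretation here).
3. **Mixing.** $W'$ binarizes $W_{trg}$ (1 at each column maximum), and
   $$X_{trg}^{new} = \theta\, H W' + (1-\theta) X_{trg},
     \qquad 0 \le \theta \le 1 .$$
   At $\theta = 0$ the target is untouched; at $\theta = 1$ each target
   cell is replaced by its assigned source centroid.
4. **Clustering.** $X_{trg}^{new}$ goes to an SC3-style consensus
   clusterer (k-means over Euclidean/Pearson/Spearman distances under PCA
   and graph-Laplacian transforms, averaged into a consensus matrix, cut
   by complete-linkage hierarchical clustering).

### Choosing the mixture weight

$\theta$ is selected from a grid by kernel target alignment (KTA): for
each candidate, the pipeline is run and the predicted labeling is scored
by the normalized Frobenius inner product between the label kernel and a
data kernel; the best-scoring $\theta$ wins (ties to the smallest value).

Which data kernel matters. Scoring the labels against the kernel of the
mixed data itself is self-fulfilling at high $\theta$: $HW'$ has exactly
one distinct column per atom, the clusterer reproduces the atom
assignment verbatim, and the alignment is maximal whether or not the
source resembles the target — a dissimilar source could then never be
rejected. `sctransfer` therefore scores each candidate labeling against
the **centered linear kernel of the original target data**: the selected
$\theta$ is the one whose induced labeling best explains the geometry the
target actually has. Centering removes the constant component that
dominates inner products of nonnegative expression profiles and would
otherwise swamp the cluster signal. Both choices are exposed
(`score_on`, `center_kernels`); the defaults are the combination that, in
our simulations, both rewards genuine transfer under overlapping
source/target populations and selects a low $\theta$ when the
populations are disjoint.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 1.0 | elastic-net penalty multiplier (objective units) |
| `lam` | 0.5 | L1/L2 mixing, in [0, 1] |
| `k` (dictionary) | — | number of source clusters (label count) |
| `k` (clusterer) | — | clusters sought in the target; may differ |
| `theta_grid` | 0, 0.1, …, 1 | candidate mixture weights |
| `metrics` | all three | SC3 distance measures |
| `d_range` | 4–7% of n | embedding dimensions (SC3 convention) |
| `kmeans_restarts` | 10 | random starts per embedding |

The dictionary `k` follows the source label count while the clusterer `k`
is set independently (a target may be probed for a different number of
clusters than the source has — e.g. a 7-cluster target against an
11-type reference).

## Pre-processing

Three steps, applied once per dataset (source and target separately),
then gene-space intersection:

1. **Cell filter** — drop cells with fewer than `x_genes` genes above
   `x_expression`.
2. **Gene filter** — drop *ubiquitous* genes (above `x_expression` in at
   least `x_cells`% of cells) and *rare* genes (below `x_expression` in
   at least `x_cells`% of cells). Comparisons are strict; a value exactly
   at the threshold counts toward neither rule.
3. **Log transform** — $\log_2(v+1)$; base 2 matches the fold-change
   convention of the simulator, other bases are available.

Threshold defaults (`x_genes = 2000`, `x_expression = 0`,
`x_cells = 94`) are generic starting points; real datasets need
thresholds chosen from their expression histograms.

## The count simulator

`generate_dataset()` draws count-level data from a fixed hierarchy of
eight leaf cell clusters under five top-level clusters: three top nodes
are themselves leaves, the remaining two split into two and three
sub-clusters respectively (which two/three-way split is attached to
which node is an encoding choice; it does not affect any statistic
computed here). Generation:

* leaf cluster sizes: symmetric Dirichlet (concentration 10), converted
  to integers by largest-remainder rounding with at least one cell each;
* background per-gene mean: Gamma(shape 2, rate 0.1);
* per node, a uniform 10–40% of genes receive a log2 fold change drawn
  from Normal(1, 0.5) with random sign, applied recursively with the
  parent profile as the new background;
* per-entry multiplicative Gaussian noise (SD 10% of the expression
  level, truncated at zero);
* counts: negative binomial with dispersion 0.1 in the
  $\mathrm{var} = \mu + 0.1\mu^2$ convention (dispersion 0 gives
  Poisson).

With the default scale (10 000 genes, 1800 cells) the median total count
per cell lands near 215 500 — the calibration anchor. Both the random
fold-change sign and the modest noise SD are consistent with that anchor:
all-upward fold changes would push the median ~19% high, and a large
truncated noise SD inflates the mean noise factor above 1.

Datasets are split into source and target under three regimes —
`complete` (every top node on both sides), `incomplete` (three shared
top nodes, one exclusive to each side), `none` (two top nodes form the
target, the other three the source) — with top nodes re-randomized per
repetition, and targets downsampled to the sizes under study.

What the simulator does **not** emulate: zero-inflation/dropout beyond
the NB model, per-cell library-size variation, doublets, batch effects,
or gene-gene correlation beyond the cluster structure. Passing tests on
simulated data therefore show that the machinery behaves as designed
under the stated generative model, not that it will improve any
particular real dataset.

## Evaluation harness

`run_simulation_study()` wires everything together per repetition:
generate, split, pre-process each side (cell filter, gene filter with the
prevalence rule, log transform), intersect genes, downsample the target,
run TargetCluster / ConcatenateCluster / TransferCluster, and score the
adjusted Rand index of predicted vs true target labels (always on target
cells only). Aggregates are means with normal-approximation 95%
confidence intervals across repetitions; a percentile bootstrap was
considered and rejected as overkill at 10–100 repetitions.

The harness filter defaults scale with the simulation
(`x_genes = 0.2 * n_genes`, `x_expression = 0`, `x_cells = 94`; at the
full 10 000-gene scale this is exactly the shipped 2000-gene default).
With `x_expression = 0` the gene filter removes genes detected in ≥94%
of cells — for deeply sequenced simulated counts that is most of them —
leaving the sparse low-expression genes. This matters: on the unfiltered
gene set every method clusters the simulated data perfectly and no
comparison is informative; the filtered, sparse gene space is the regime
in which the methods separate.

`robustness_count()` implements the repeated-run counting protocol for
non-deterministic clusterers: a criterion is a set of disjoint reference
cell groups, "identified" in a run when the groups' majority predicted
clusters are pairwise distinct (the predicate is pluggable; majority
separation is our reading of "successfully identified", which the
original description leaves undefined).

## Problem sizes used in the shipped validation

The packaged tests and `scripts/acceptance.R` run:

* simulator calibration at the full default scale (10 000 × 1800), one
  dataset;
* the complete-overlap comparison at 2000 genes, 900 cells (500 source),
  10 repetitions, target sizes 100 and 400, grid
  {0, 0.25, 0.5, 0.75, 1};
* the no-overlap comparison at the same scale, target size 100.

These sizes keep a full validation run in minutes on one CPU. One
consequence is worth stating plainly: the simulated clustering problem
gets *easier* as the gene count grows (more informative genes survive
filtering), and near the performance ceiling the three methods converge.
At the sizes above, TransferCluster beats TargetCluster and transfer is
safe under no overlap (low $\theta$ selected, no performance loss, while
ConcatenateCluster collapses); but ConcatenateCluster, which under
*complete* overlap amounts to clustering the target jointly with an
easily-clustered source, sits at the same ceiling and is not reliably
surpassed. The advantage of true source labels over re-clustering the
source only has room to appear when the source itself is hard to
cluster — a sub-ceiling regime this generative model does not reach at
desk scale. The no-overlap and incomplete-overlap contrasts, where
concatenation actively hurts, do not depend on that regime and reproduce
cleanly.

## Numerical choices and degenerate inputs

* NMF updates are exact per-column (HALS-style) minimizations, so the
  objective is non-increasing by construction; convergence is declared at
  relative objective change below `tol` (default 1e-5) or `max_iter`
  (500). A zero-norm factor column is set to zero rather than divided by.
* The per-column NNLS in the transfer step iterates cyclic coordinate
  descent to a 1e-10 coordinate-change tolerance.
* Ties in `binarize_assignments()` and in label argmaxes go to the lowest
  row index; ties in KTA scores to the smallest $\theta$.
* Correlation distances treat a constant cell profile as correlation 0
  (distance 1) instead of NA.
* A clusterer failure at one grid $\theta$ (e.g. fewer distinct columns
  than clusters at $\theta = 1$) drops that grid point with a warning;
  only an all-grid failure is an error.
* All stochastic stages (simulator, NMF random init, k-means) take
  explicit seeds; repetition harnesses derive per-repetition substreams.

## Known limitations

* The SC3 stage is a reconstruction of the published SC3 recipe
  (distances, transforms, consensus, complete-linkage cut) with all
  settings exposed; it is not a wrapper around the SC3 package, and
  d-ranges/restart counts default to light-weight values appropriate for
  a few hundred cells.
* Transfer across different gene spaces is out of scope; source and
  target are always intersected first.
* No automatic choice of the cluster count k.
* The simulator's noise scale and fold-change sign convention are fixed
  by the calibration anchor, not by a published specification.
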