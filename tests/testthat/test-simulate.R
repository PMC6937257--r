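test_that("cluster tree matches the fixed five-top-node/eight-leaf topology", {
  tree <- cluster_tree()
  expect_length(tree$top_nodes, 5)
  expect_length(tree$leaves, 8)
  expect_setequal(names(tree$leaf_top), as.character(1:8))
  expect_true(all(tree$leaf_top %in% tree$top_nodes))
  # every top node owns at least one leaf; V, W, X are singleton leaves
  expect_setequal(unique(tree$leaf_top), tree$top_nodes)
  expect_equal(sum(table(tree$leaf_top) > 1), 2)   # two multi-leaf tops
})

test_that("cluster sizes are positive integers conserving the total", {
  for (seed in 1:5) {
    s <- sample_cluster_sizes(800, 8, concentration = 10, seed = seed)
    expect_equal(sum(s), 800)
    expect_true(all(s >= 1))
  }
  expect_equal(sample_cluster_sizes(8, 8, concentration = 1e9, seed = 1),
               rep(1L, 8))
  expect_error(sample_cluster_sizes(5, 8), "at least")
})

test_that("Dirichlet cluster sizes have the symmetric mean (Monte Carlo)", {
  draws <- withr::with_seed(99, {
    t(replicate(10000, sample_cluster_sizes(800, 8, concentration = 10)))
  })
  means <- colMeans(draws)
  # per-leaf mean 100; sd of a single draw ~ 800*sqrt(p(1-p)/(80+1))
  se <- 800 * sqrt((1 / 8) * (7 / 8) / 81) / sqrt(nrow(draws))
  expect_true(all(abs(means - 100) < 3 * se))
})

test_that("generated counts are nonnegative integers, deterministic by seed", {
  cfg <- sim_config(n_genes = 200, n_cells = 60, n_src = 30, seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$X[, ], d2$X[, ])
  expect_identical(d1$y, d2$y)
  v <- unclass(d1$X)
  expect_true(all(v >= 0))
  expect_true(all(v == round(v)))
  expect_length(d1$y, 60)
  expect_true(all(d1$y %in% 0:7))
})

test_that("dispersion zero gives Poisson-like counts (variance ~ mean)", {
  cfg <- sim_config(n_genes = 2000, n_cells = 100, n_src = 50,
                    nb_dispersion = 0, cell_noise_sd = 0, seed = 3)
  d <- generate_dataset(cfg)
  v <- unclass(d$X)[, d$y == d$y[1], drop = FALSE]   # one cluster
  m <- rowMeans(v)
  s2 <- apply(v, 1, stats::var)
  keep <- m > 5
  # index of dispersion ratio concentrates near 1 for Poisson
  expect_lt(abs(median(s2[keep] / m[keep]) - 1), 0.1)
})

test_that("negative binomial counts are overdispersed at dispersion 0.1", {
  cfg <- sim_config(n_genes = 2000, n_cells = 100, n_src = 50,
                    nb_dispersion = 0.1, cell_noise_sd = 0, seed = 3)
  d <- generate_dataset(cfg)
  v <- unclass(d$X)[, d$y == d$y[1], drop = FALSE]
  m <- rowMeans(v)
  s2 <- apply(v, 1, stats::var)
  keep <- m > 20
  # var = mu + 0.1 mu^2 => (var - mu)/mu^2 ~ 0.1
  phi <- median((s2[keep] - m[keep]) / m[keep]^2)
  expect_lt(abs(phi - 0.1), 0.05)
})

test_that("non-DE genes keep the background expectation within a leaf", {
  # with DE fraction forced tiny, cluster means track the background
  cfg <- sim_config(n_genes = 1000, n_cells = 200, n_src = 100,
                    de_fraction_range = c(0.001, 0.001),
                    cell_noise_sd = 0, seed = 8)
  d <- generate_dataset(cfg)
  v <- unclass(d$X)
  m1 <- rowMeans(v[, d$y == 0, drop = FALSE])
  m2 <- rowMeans(v[, d$y == 3, drop = FALSE])
  # overwhelming majority of genes agree across clusters
  agree <- mean(abs(m1 - m2) / (1 + (m1 + m2) / 2) < 0.5)
  expect_gt(agree, 0.95)
})

test_that("splits partition cells and respect the overlap regime", {
  d <- small_sim(seed = 21, n_genes = 100, n_cells = 400)
  tops <- function(ds) unique(ds$top_node_of[ds$y + 1])

  sp <- split_source_target(d, "complete", 200, 200, seed = 1)
  expect_length(intersect(cell_ids(sp$source$X), cell_ids(sp$target$X)), 0)
  expect_setequal(tops(sp$source), c("V", "W", "X", "Y", "Z"))
  expect_setequal(tops(sp$target), c("V", "W", "X", "Y", "Z"))

  sp <- split_source_target(d, "incomplete", seed = 2)
  shared <- intersect(tops(sp$source), tops(sp$target))
  expect_length(shared, 3)
  expect_length(setdiff(tops(sp$source), tops(sp$target)), 1)
  expect_length(setdiff(tops(sp$target), tops(sp$source)), 1)
  expect_length(intersect(cell_ids(sp$source$X), cell_ids(sp$target$X)), 0)

  sp <- split_source_target(d, "none", seed = 3)
  expect_length(intersect(tops(sp$source), tops(sp$target)), 0)
  expect_length(tops(sp$source), 3)
  expect_length(tops(sp$target), 2)

  expect_error(split_source_target(d, "none", n_src = 1e6, seed = 4),
               "exceed")
})

test_that("top-node assignment is re-randomized across repetitions", {
  d <- small_sim(seed = 22, n_genes = 50, n_cells = 300)
  tops <- sapply(1:12, function(s) {
    sp <- split_source_target(d, "none", seed = s)
    paste(sort(unique(sp$target$top_node_of[sp$target$y + 1])),
          collapse = "")
  })
  expect_gt(length(unique(tops)), 1)
})

test_that("downsample draws a uniform subset with labels carried along", {
  d <- small_sim(seed = 23, n_genes = 20, n_cells = 80)
  expect_identical(downsample(d, ncol(d$X), seed = 1)$X[, ], d$X[, ])

  one <- downsample(d, 1, seed = 2)
  expect_length(one$y, 1)
  expect_identical(names(one$y), cell_ids(one$X))
  expect_identical(unname(one$y), unname(d$y[cell_ids(one$X)]))

  expect_error(downsample(d, 81), "cannot downsample")

  # inclusion frequency ~ n/N (hypergeometric marginal)
  freq <- withr::with_seed(77, {
    counts <- numeric(ncol(d$X))
    names(counts) <- cell_ids(d$X)
    for (r in 1:400) {
      idx <- cell_ids(downsample(d, 40)$X)
      counts[idx] <- counts[idx] + 1
    }
    counts / 400
  })
  expect_true(all(abs(freq - 0.5) < 4 * sqrt(0.25 / 400)))
})
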