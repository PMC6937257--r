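test_that("ARI matches hand-evaluated and reference values", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(5, 5, 2, 2)), 1)
  # hand evaluation of the contingency formula
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
  expect_error(adjusted_rand_index(1, 1), "at least 2")
})

test_that("ARI is symmetric and agrees with mclust on random partitions", {
  skip_if_not_installed("mclust")
  withr::with_seed(61, {
    for (i in 1:20) {
      a <- sample(0:4, 30, replace = TRUE)
      b <- sample(0:3, 30, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
  })
})

test_that("TargetCluster is consensus clustering of the target alone", {
  blobs <- two_blob_data(n_per = 7, sep = 20, seed = 63)
  cfg <- sc3_config(k = 2, seed = 19)
  expect_identical(target_cluster(blobs$x, cfg),
                   consensus_cluster(blobs$x, cfg))
  expect_equal(adjusted_rand_index(target_cluster(blobs$x, cfg),
                                   blobs$truth), 1)
})

test_that("ConcatenateCluster returns target labels only", {
  blobs <- two_blob_data(n_per = 6, sep = 20, seed = 67)
  v <- unclass(blobs$x)
  src <- v[, 1:4, drop = FALSE]
  cfg <- sc3_config(k = 2, seed = 21)

  lab <- concatenate_cluster(src, v, cfg)
  expect_length(lab, ncol(v))
  expect_identical(names(lab), colnames(v))

  # empty source degenerates to TargetCluster
  empty <- v[, integer(0), drop = FALSE]
  expect_identical(unname(concatenate_cluster(empty, v, cfg)),
                   unname(target_cluster(v, cfg)))

  # source = copy of target: each target cell co-clusters with its twin
  lab2_all <- consensus_cluster(
    {m <- cbind(v, v); colnames(m) <- make.unique(colnames(m)); m},
    cfg)
  expect_equal(adjusted_rand_index(lab2_all[1:ncol(v)],
                                   lab2_all[ncol(v) + 1:ncol(v)]), 1)

  expect_error(concatenate_cluster(matrix(1, 3, 2), matrix(1, 4, 2), cfg),
               "gene spaces differ")
})

test_that("simulation study output honours the row-count contract", {
  res <- quiet(run_simulation_study(
    sim = sim_config(n_genes = 300, n_cells = 160, n_src = 80, seed = 0),
    modes = "complete",
    methods = c("TargetCluster", "TransferCluster"),
    target_sizes = c(30, 60), n_reps = 2, seed = 3,
    theta_grid = c(0, 1),
    sc3_args = list(kmeans_restarts = 3)))
  expect_equal(nrow(res$results), 2 * 1 * 2 * 2)
  expect_true(all(res$results$ari <= 1))
  expect_true(all(c("rep", "mode", "method", "n_trg", "ari",
                    "theta_star") %in% names(res$results)))
  # theta recorded for the transfer method only
  expect_true(all(is.na(
    res$results$theta_star[res$results$method == "TargetCluster"])))
  expect_true(all(!is.na(
    res$results$theta_star[res$results$method == "TransferCluster"])))
  # aggregate has a CI for n >= 2 repetitions
  expect_true(all(res$summary$n == 2))
  expect_true(all(is.finite(res$summary$ci95)))
})

test_that("a single repetition yields no confidence interval", {
  res <- quiet(run_simulation_study(
    sim = sim_config(n_genes = 200, n_cells = 120, n_src = 60, seed = 0),
    modes = "complete", methods = "TargetCluster",
    target_sizes = 30, n_reps = 1, seed = 5,
    sc3_args = list(kmeans_restarts = 2)))
  expect_true(all(is.na(res$summary$ci95)))
})

test_that("CI half-width shrinks roughly like 1/sqrt(reps)", {
  withr::with_seed(71, fake_ari <- rnorm(80, 0.8, 0.05))
  mk <- function(n) data.frame(rep = seq_len(n), mode = "complete",
                               method = "TargetCluster", n_trg = 100,
                               ari = fake_ari[seq_len(n)],
                               theta_star = NA_real_)
  ci20 <- sctransfer:::aggregate_results(mk(20))$ci95
  ci80 <- sctransfer:::aggregate_results(mk(80))$ci95
  expect_lt(ci80, ci20 / 1.5)
})

test_that("experiment rows are reproducible from config and seed", {
  args <- list(sim = sim_config(n_genes = 200, n_cells = 120, n_src = 60,
                                seed = 0),
               modes = "none", methods = "TargetCluster",
               target_sizes = 25, n_reps = 1, seed = 11,
               sc3_args = list(kmeans_restarts = 2))
  r1 <- quiet(do.call(run_simulation_study, args))
  r2 <- quiet(do.call(run_simulation_study, args))
  expect_identical(r1$results, r2$results)
})

test_that("separation criteria validate and count successes", {
  expect_error(separation_criterion(list(a = "c1")), "length")
  expect_error(separation_criterion(list(a = "c1", b = character(0))),
               "non-empty")
  expect_error(separation_criterion(list(a = "c1", b = "c1")), "disjoint")

  crit <- separation_criterion(list(a = c("c1", "c2"), b = c("c3", "c4")))
  sep <- stats::setNames(c(0L, 0L, 1L, 1L), paste0("c", 1:4))
  mixed <- stats::setNames(c(0L, 0L, 0L, 1L), paste0("c", 1:4))
  expect_true(sctransfer:::criterion_met(crit, sep))
  # majority cluster of b is 0 or 1 (tie): table order picks 0 -> not split
  expect_false(sctransfer:::criterion_met(crit, mixed))

  always <- separation_criterion(list(a = "c1", b = "c2"),
                                 rule = function(labels) TRUE)
  method <- function(seed) sep
  counts <- robustness_count(method, list(always = always, split = crit),
                             n_reps = 5, seed = 1)
  expect_equal(as.vector(counts), c(5L, 5L))
  expect_equal(attr(counts, "n_reps"), 5)

  # deterministic method: counts are all-or-nothing
  expect_true(all(counts %in% c(0L, 5L)))
  expect_error(robustness_count(method, list(always), n_reps = 0),
               "at least 1")

  # failing repetitions count as non-success
  flaky <- function(seed) stop("boom")
  expect_equal(as.vector(robustness_count(flaky, list(always), n_reps = 3)),
               0L)
})
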