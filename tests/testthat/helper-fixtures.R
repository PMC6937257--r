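# Shared fixture builders; everything is generated in code.

toy_matrix <- function(g = 3, n = 2, seed = 1, unit = "counts") {
  withr::with_seed(seed, {
    m <- matrix(rpois(g * n, 5), g, n,
                dimnames = list(paste0("g", seq_len(g)),
                                paste0("c", seq_len(n))))
    expr_matrix(m, unit = unit)
  })
}

# Two well-separated cell populations with distinct per-gene profiles
# (separable under euclidean AND correlation metrics), genes x cells.
two_blob_data <- function(n_per = 10, g = 20, sep = 20, seed = 1) {
  withr::with_seed(seed, {
    mu_a <- runif(g, 0, sep)
    mu_b <- runif(g, 0, sep)
    a <- mu_a + matrix(rnorm(g * n_per), g, n_per)
    b <- mu_b + matrix(rnorm(g * n_per), g, n_per)
    m <- pmax(cbind(a, b), 0)
    dimnames(m) <- list(paste0("g", seq_len(g)),
                        paste0("c", seq_len(2 * n_per)))
    list(x = expr_matrix(m, unit = "log"),
         truth = rep(0:1, each = n_per))
  })
}

# A small labeled simulated dataset (already generated counts).
small_sim <- function(seed = 5, n_genes = 300, n_cells = 120) {
  generate_dataset(sim_config(n_genes = n_genes, n_cells = n_cells,
                              n_src = floor(n_cells / 2), seed = seed))
}

quiet <- function(expr) suppressWarnings(expr)

within_iter <- function(cfg, n) {
  cfg$max_iter <- as.integer(n)
  cfg
}
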