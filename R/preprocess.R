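#' Pre-processing configuration
#'
#' Thresholds for the three-step quality-control pipeline applied to each
#' dataset (source and target separately) before any clustering: a cell
#' filter, a gene filter, and a log transform.
#'
#' @param x_genes Minimum number of detected genes a cell must have
#'   (detected means expression strictly greater than `x_expression`).
#' @param x_expression Detection threshold on the expression value.
#' @param x_cells Prevalence threshold in percent, strictly between 0
#'   and 100, used by the gene filter.
#'
#' @details The defaults (`x_genes = 2000`, `x_expression = 0`,
#'   `x_cells = 94`) are generic starting points; thresholds should be chosen
#'   per dataset from expression histograms and passed explicitly.
#'
#' @return A `filter_config` list.
#' @export
filter_config <- function(x_genes = 2000, x_expression = 0, x_cells = 94) {
  stopifnot(x_genes >= 1, x_expression >= 0, x_cells > 0, x_cells < 100)
  structure(list(x_genes = as.integer(x_genes),
                 x_expression = x_expression,
                 x_cells = x_cells),
            class = "filter_config")
}

#' Cell filter
#'
#' Removes cells expressing too few genes: a cell is kept iff the number of
#' its entries strictly greater than `x_expression` is at least `x_genes`.
#' The gene set and the order of the surviving cells are unchanged.
#'
#' @param x An [expr_matrix].
#' @param cfg A [filter_config].
#' @return The filtered [expr_matrix].
#' @export
cell_filter <- function(x, cfg = filter_config()) {
  x <- as_expr(x)
  detected <- colSums(unclass(x) > cfg$x_expression)
  keep <- detected >= cfg$x_genes
  if (!any(keep))
    stop("empty after filtering: no cell passes the cell filter",
         call. = FALSE)
  subset_expr(x, cells = which(keep))
}

#' Gene filter
#'
#' Removes ubiquitous genes (expression strictly above `x_expression` in at
#' least `x_cells`% of cells) and rare genes (expression strictly below
#' `x_expression` in at least `x_cells`% of cells). Gene order is preserved.
#'
#' @inheritParams cell_filter
#' @return The filtered [expr_matrix].
#' @export
gene_filter <- function(x, cfg = filter_config()) {
  x <- as_expr(x)
  v <- unclass(x)
  n <- ncol(v)
  cut <- cfg$x_cells / 100 * n
  ubiquitous <- rowSums(v > cfg$x_expression) >= cut
  rare <- rowSums(v < cfg$x_expression) >= cut
  keep <- !(ubiquitous | rare)
  if (!any(keep))
    stop("empty after filtering: no gene passes the gene filter",
         call. = FALSE)
  subset_expr(x, genes = which(keep))
}

#' Log transform
#'
#' Replaces every entry v by `log(v + 1)` (pseudo-count of 1) in the given
#' base and tags the matrix as log-scaled. Applying it twice is an error.
#'
#' @param x An [expr_matrix] not already on the log scale.
#' @param base Logarithm base; base 2 by default, consistent with the log2
#'   fold changes used elsewhere in the package.
#' @return The transformed [expr_matrix] with unit `"log"`.
#' @export
log_transform <- function(x, base = 2) {
  x <- as_expr(x)
  if (expr_unit(x) == "log")
    stop("matrix is already log-transformed", call. = FALSE)
  expr_matrix(log(unclass(x) + 1, base = base),
              gene_ids(x), cell_ids(x), unit = "log")
}

#' Restrict two datasets to their common genes
#'
#' Source and target must live in the same gene space before any transfer;
#' both matrices are restricted to the intersection of their gene ids, with
#' rows in identical order (the order of appearance in `a`).
#'
#' @param a,b [expr_matrix] objects.
#' @return A list with elements `a` and `b`, both over the shared genes.
#' @export
intersect_genes <- function(a, b) {
  a <- as_expr(a); b <- as_expr(b)
  shared <- intersect(gene_ids(a), gene_ids(b))
  if (length(shared) == 0L)
    stop("no genes shared between the two datasets", call. = FALSE)
  list(a = subset_expr(a, genes = match(shared, gene_ids(a))),
       b = subset_expr(b, genes = match(shared, gene_ids(b))))
}

#' Full pre-processing pipeline
#'
#' Applies, in this order: cell filter, gene filter, log transform. Run once
#' per dataset (source and target separately) before clustering or transfer.
#'
#' @inheritParams cell_filter
#' @param log Apply the final log transform (default `TRUE`).
#' @param base Log base passed to [log_transform()].
#' @return The pre-processed [expr_matrix].
#' @export
preprocess <- function(x, cfg = filter_config(), log = TRUE, base = 2) {
  x <- gene_filter(cell_filter(x, cfg), cfg)
  if (log) x <- log_transform(x, base = base)
  x
}
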