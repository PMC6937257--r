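#' Expression matrix container
#'
#' A light S3 wrapper around a nonnegative genes-by-cells numeric matrix with
#' unique gene and cell identifiers and a unit tag recording the expression
#' scale (counts, TPM, CPM, RPKM, or log after transformation).
#'
#' @param values Numeric matrix, genes in rows, cells in columns. All entries
#'   must be finite and nonnegative.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#'   Defaults to the matrix rownames.
#' @param cell_ids Character vector of unique cell identifiers, one per
#'   column. Defaults to the matrix colnames.
#' @param unit One of `"counts"`, `"tpm"`, `"cpm"`, `"rpkm"`, `"log"`.
#'
#' @return An object of class `expr_matrix`: the numeric matrix with
#'   dimnames set and a `unit` attribute.
#' @export
#'
#' @examples
#' m <- matrix(rpois(6, 5), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:2)))
#' x <- expr_matrix(m, unit = "counts")
#' gene_ids(x)
expr_matrix <- function(values, gene_ids = rownames(values),
                        cell_ids = colnames(values), unit = "counts") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  unit <- match.arg(unit, c("counts", "tpm", "cpm", "rpkm", "log"))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) must equal nrow(values)", call. = FALSE)
  if (length(cell_ids) != ncol(values))
    stop("length(cell_ids) must equal ncol(values)", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("gene identifiers must be unique", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("cell identifiers must be unique", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing", call. = FALSE)
  if (any(values < 0))
    stop("expression values must be nonnegative", call. = FALSE)
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(values, unit = unit, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
gene_ids <- function(x) rownames(x)

#' @rdname expr_matrix
#' @export
cell_ids <- function(x) colnames(x)

#' @rdname expr_matrix
#' @export
expr_unit <- function(x) attr(x, "unit") %||% "counts"

#' @method print expr_matrix
#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d cells [%s]\n",
              nrow(x), ncol(x), expr_unit(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subset an expr_matrix keeping class/unit metadata intact.
subset_expr <- function(x, genes = NULL, cells = NULL) {
  v <- unclass(x)
  attr(v, "unit") <- NULL
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(cells)) v <- v[, cells, drop = FALSE]
  expr_matrix(v, unit = expr_unit(x))
}

as_expr <- function(x, unit = "counts") {
  if (inherits(x, "expr_matrix")) return(x)
  expr_matrix(as.matrix(x), unit = unit)
}
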