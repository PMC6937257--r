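#' Read an expression matrix from disk
#'
#' Supports dense TSV/CSV (first column gene id, header row of cell ids) and
#' MatrixMarket coordinate format with `genes.txt` / `cells.txt` sidecar files
#' (one identifier per line) next to the `.mtx` file.
#'
#' @param path Path to the matrix file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`. Defaults to a guess from
#'   the file extension.
#' @param unit Expression unit tag to attach (`"counts"`, `"tpm"`, `"cpm"`,
#'   `"rpkm"`, `"log"`).
#' @param transpose If `TRUE` the file is cells-by-genes and is transposed
#'   on read.
#'
#' @return An [expr_matrix].
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, format = c("guess", "tsv", "csv", "mtx"),
                        unit = "counts", transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", "tsv")
  }
  if (format == "mtx") {
    side <- function(name) {
      p <- file.path(dirname(path), name)
      if (!file.exists(p))
        stop(sprintf("missing sidecar file: %s", p), call. = FALSE)
      readLines(p)
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- side("genes.txt")
    cells <- side("cells.txt")
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("sidecar identifier counts do not match matrix dimensions",
           call. = FALSE)
    rownames(m) <- genes
    colnames(m) <- cells
  } else {
    sep <- if (format == "csv") "," else "\t"
    first <- readLines(path, n = 1L)
    if (length(first) == 0L || !nzchar(first))
      stop(sprintf("parse error in %s: file is empty (line 1)", path),
           call. = FALSE)
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, comment.char = "")
    m <- as.matrix(df)
    if (!is.numeric(m)) {
      bad <- which(!apply(df, 2L, function(col) {
        all(!is.na(suppressWarnings(as.numeric(col))))
      }))[1L]
      stop(sprintf("parse error in %s: non-numeric value in column %d",
                   path, bad + 1L), call. = FALSE)
    }
  }
  if (transpose) m <- t(m)
  if (any(m < 0))
    stop("validation error: negative expression entries", call. = FALSE)
  expr_matrix(m, unit = unit)
}

#' Write an expression matrix to disk
#'
#' @inheritParams read_matrix
#' @param x An [expr_matrix] (or plain matrix with dimnames).
#' @param path Output path; for MTX, sidecars `genes.txt` / `cells.txt` are
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("guess", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", "tsv")
  }
  x <- as_expr(x)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(unclass(x)[, , drop = FALSE],
                                   sparse = TRUE), path)
    writeLines(gene_ids(x), file.path(dirname(path), "genes.txt"))
    writeLines(cell_ids(x), file.path(dirname(path), "cells.txt"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene = gene_ids(x), unclass(x), check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read or write per-cell cluster labels
#'
#' Labels are stored as a two-column TSV (`cell_id`, integer label); labels
#' are 0-based cluster indices.
#'
#' @param path Path to the TSV file.
#' @return `read_labels`: a named integer vector (names are cell ids).
#' @export
read_labels <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer"))
  stats::setNames(as.integer(df[[2L]]), df[[1L]])
}

#' @rdname read_labels
#' @param y Named integer label vector.
#' @export
write_labels <- function(y, path) {
  df <- data.frame(cell_id = names(y) %||% seq_along(y),
                   label = as.integer(y))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
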