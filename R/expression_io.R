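#' Read an expression matrix from disk
#'
#' Reads either a delimited table (first row = column ids, first column =
#' row ids, separator auto-detected among comma and tab) or a Matrix Market
#' coordinate file with sidecar id files `<stem>.rows.txt` / `<stem>.cols.txt`
#' (one id per line). The on-disk orientation is declared by the caller;
#' internally everything is normalised to cells x genes, the orientation the
#' whole pipeline works in. scRNA-seq matrices are conventionally distributed
#' genes x cells, hence the default.
#'
#' @param path Path to the matrix file.
#' @param orientation `"genes_by_cells"` (default; file rows are genes) or
#'   `"cells_by_genes"`.
#' @param format `"delimited"` or `"matrix_market"`.
#' @return An [expression_matrix()] (always cells x genes).
#' @export
read_matrix <- function(path,
                        orientation = c("genes_by_cells", "cells_by_genes"),
                        format = c("delimited", "matrix_market")) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path), call. = FALSE)

  if (format == "delimited") {
    sep <- detect_separator(path)
    dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
    if (ncol(dt) < 1) stop(sprintf("empty delimited file: %s", path), call. = FALSE)
    row_ids <- as.character(dt[[1]])
    vals <- as.matrix(dt[, -1, drop = FALSE])
    if (ncol(vals) > 0 && !is.numeric(vals)) {
      stop(sprintf("non-numeric entries in %s", path), call. = FALSE)
    }
    storage.mode(vals) <- "double"
    rownames(vals) <- row_ids
  } else {
    m <- Matrix::readMM(path)
    vals <- as.matrix(m)
    stem <- sub("\\.[^.]*$", "", path)
    rows_file <- paste0(stem, ".rows.txt")
    cols_file <- paste0(stem, ".cols.txt")
    if (!file.exists(rows_file) || !file.exists(cols_file)) {
      stop(sprintf("matrix_market sidecar id files missing: %s / %s",
                   rows_file, cols_file), call. = FALSE)
    }
    rownames(vals) <- readLines(rows_file)
    colnames(vals) <- readLines(cols_file)
  }

  if (orientation == "genes_by_cells") vals <- t(vals)
  expression_matrix(vals)
}

detect_separator <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) return(",")
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab >= n_com) "\t" else ","
}

#' Write an expression matrix to disk
#'
#' The inverse of [read_matrix()]: a delimited write stores the matrix in the
#' declared orientation with full double precision (17 significant digits) so
#' a read round-trip is lossless; a Matrix Market write stores only nonzeros
#' plus `<stem>.rows.txt` / `<stem>.cols.txt` sidecars.
#'
#' @param matrix An [expression_matrix()] (cells x genes).
#' @inheritParams read_matrix
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(matrix, path,
                         orientation = c("genes_by_cells", "cells_by_genes"),
                         format = c("delimited", "matrix_market")) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  matrix <- as_expr_matrix(matrix)
  vals <- unclass(matrix)
  if (orientation == "genes_by_cells") vals <- t(vals)

  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory not writable or missing: %s", dir), call. = FALSE)

  if (format == "delimited") {
    chr <- formatC(vals, digits = 17, format = "g", width = 1)
    dim(chr) <- dim(vals)
    out <- cbind(id = rownames(vals), chr)
    colnames(out) <- c("id", colnames(vals))
    ok <- tryCatch({
      utils::write.table(out, file = path, sep = ",", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop(sprintf("failed to write %s: %s", path, conditionMessage(ok)), call. = FALSE)
  } else {
    stem <- sub("\\.[^.]*$", "", path)
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(vals, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"), path)
    writeLines(rownames(vals), paste0(stem, ".rows.txt"))
    writeLines(colnames(vals), paste0(stem, ".cols.txt"))
  }
  invisible(path)
}

#' Select highly variable genes
#'
#' Keeps the `n_top` genes with the largest unbiased sample variance across
#' cells, preserving the original gene order among those selected; ties are
#' broken by original gene order. Values are ranked as-is — no implicit log
#' transform — so apply [log1p()] beforehand if a variance-on-log ranking is
#' wanted.
#'
#' @param matrix An [expression_matrix()].
#' @param n_top Number of genes to keep (clamped to the number available).
#' @return An [expression_matrix()] with at most `n_top` genes; cells
#'   unchanged.
#' @export
#'
#' @examples
#' m <- expression_matrix(cbind(a = c(1, 1, 1), b = c(0, 4, 8), c = c(0, 1, 2)))
#' gene_ids(select_hvg(m, 2))
select_hvg <- function(matrix, n_top) {
  matrix <- as_expr_matrix(matrix)
  if (length(n_top) != 1 || !is.finite(n_top) || n_top < 1) {
    stop("`n_top` must be a positive integer", call. = FALSE)
  }
  s <- ncol(matrix)
  n_top <- min(as.integer(n_top), s)
  if (n_top == s) return(matrix)
  v <- apply(unclass(matrix), 2, stats::var)
  keep <- sort(order(-v, seq_len(s))[seq_len(n_top)])
  matrix[, keep, drop = FALSE]
}

#' Read / write per-cell labels
#'
#' Labels files hold one label per line, in the same order as the matrix's
#' cell ids.
#'
#' @param path Path to the labels file.
#' @return For `read_labels`, a character vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("labels file not found: %s", path), call. = FALSE)
  readLines(path)
}

#' @rdname read_labels
#' @param labels Character (or coercible) vector of per-cell labels.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}
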