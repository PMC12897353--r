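#' Construct an expression matrix
#'
#' The package's universal data container: a non-negative numeric matrix with
#' cells as rows and genes as columns, carrying cell and gene identifiers as
#' dimnames. All pipeline stages consume and produce this orientation.
#'
#' @param values Numeric matrix, cells x genes, all entries finite and >= 0.
#' @param cell_ids Character vector of unique cell identifiers, one per row.
#'   Defaults to existing rownames or `cell_1..cell_y`.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column. Defaults to existing colnames or `gene_1..gene_s`.
#'
#' @return A numeric matrix of class `expr_matrix` with rownames = cell ids
#'   and colnames = gene ids.
#' @export
#'
#' @examples
#' m <- expression_matrix(matrix(0:5, nrow = 2))
#' n_cells(m)
#' n_genes(m)
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values) %||% default_ids("cell_", nrow(values))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values) %||% default_ids("gene_", ncol(values))
  }
  dimnames(values) <- list(as.character(cell_ids), as.character(gene_ids))
  class(values) <- c("expr_matrix", class(matrix()))
  validate_expr_matrix(values)
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_ids <- function(prefix, n) {
  if (n == 0) character(0) else paste0(prefix, seq_len(n))
}

validate_expr_matrix <- function(x) {
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "expression matrix must be finite and non-negative; offending entry at cell row %d ('%s'), gene column %d ('%s'): %s",
      i, rownames(x)[i], j, colnames(x)[j], format(x[i, j])
    ), call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate cell ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate gene ids", call. = FALSE)
  invisible(x)
}

#' Coerce to an expression matrix
#'
#' @param x A numeric matrix (any orientation accepted as-is) or an existing
#'   `expr_matrix`.
#' @return An `expr_matrix`.
#' @export
as_expr_matrix <- function(x) {
  if (inherits(x, "expr_matrix")) return(x)
  expression_matrix(as.matrix(x))
}

#' @rdname expression_matrix
#' @param x An `expr_matrix`.
#' @export
n_cells <- function(x) nrow(x)

#' @rdname expression_matrix
#' @export
n_genes <- function(x) ncol(x)

#' @rdname expression_matrix
#' @export
cell_ids <- function(x) rownames(x)

#' @rdname expression_matrix
#' @export
gene_ids <- function(x) colnames(x)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes\n", nrow(x), ncol(x)))
  if (nrow(x) > 0 && ncol(x) > 0) {
    i <- seq_len(min(5L, nrow(x)))
    j <- seq_len(min(5L, ncol(x)))
    print(unclass(x)[i, j, drop = FALSE])
    if (nrow(x) > 5L || ncol(x) > 5L) cat("...\n")
  }
  invisible(x)
}

# drop the class when subsetting would change semantics; keep plain matrix ops
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("expr_matrix", class(matrix()))
  out
}
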