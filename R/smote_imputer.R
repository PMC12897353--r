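#' Geometric distribution mass function
#'
#' `P(X = x) = (1 - p)^(x - 1) * p` on the positive integers; the source of
#' the raw imputation weights, under the "number of trials" convention
#' (support 1, 2, 3, ...).
#'
#' @param p Success probability in (0, 1].
#' @param x Positive integer (vectorised).
#' @return The probability mass at `x`.
#' @export
#'
#' @examples
#' geometric_pmf(0.5, 1:3)  # 0.5 0.25 0.125
geometric_pmf <- function(p, x) {
  if (length(p) != 1 || !is.finite(p) || p <= 0 || p > 1) {
    stop("`p` must be a probability in (0, 1]", call. = FALSE)
  }
  if (any(x < 1) || any(x != round(x))) {
    stop("`x` must be positive integer(s)", call. = FALSE)
  }
  (1 - p)^(x - 1) * p
}

#' Geometric parameter for a cluster-size expectation
#'
#' `p = NUM / (shrink * y)`, so the expected value `1/p = shrink * y / NUM`
#' equals the shrunken expected cluster size. Clamped to at most 1 (with a
#' warning) when the cluster count exceeds the shrunken cell count.
#'
#' @param num_clusters Number of predicted clusters (NUM >= 1).
#' @param shrink Shrinkage coefficient in (0, 1].
#' @param y Cell count (y >= num_clusters).
#' @return The geometric parameter p in (0, 1].
#' @export
#'
#' @examples
#' layer_parameter(5, 0.9, 430)  # 5/387, expectation ~77.4 cells
layer_parameter <- function(num_clusters, shrink, y) {
  stopifnot(num_clusters >= 1, y >= num_clusters)
  if (shrink <= 0 || shrink > 1) stop("`shrink` must be in (0, 1]", call. = FALSE)
  p <- num_clusters / (shrink * y)
  if (p > 1) {
    warning("NUM > shrink * y; geometric parameter clamped to 1")
    p <- 1
  }
  p
}

#' Sample random imputation weights for one target cell
#'
#' Cells are taken in similarity order (most similar first, self excluded).
#' The cell at similarity rank r receives the geometric mass
#' `geometric_pmf(p, r - 1)` — nearest neighbour gets `pmf(1)` — except that
#' masses are randomly permuted within consecutive blocks of `window`
#' neighbouring ranks, so a cell's weight is drawn from those assigned to
#' similarly ranked cells rather than strictly by rank. Raw masses are then
#' rescaled to sum exactly to `re`, the total external mass the target
#' borrows.
#'
#' @param ordering Integer vector of all y cell indices ordered by similarity
#'   to the target, target itself first (a row of
#'   [consensus_orderings()]).
#' @param p Geometric parameter in (0, 1].
#' @param re Total external weight mass RE in \[0, 1\] (0 = keep self
#'   untouched; default 0.9).
#' @param window Block size for the local weight shuffle (1 =
#'   deterministic rank-ordered weights).
#' @return Numeric y-vector of weights `f_ij` indexed by cell, 0 at the
#'   target's own position, summing to `re`.
#' @export
sample_weights <- function(ordering, p, re = 0.9, window = 4) {
  y <- length(ordering)
  if (re < 0 || re > 1) stop("`re` must be in [0, 1]", call. = FALSE)
  if (window < 1) stop("`window` must be a positive integer", call. = FALSE)
  weights <- numeric(y)
  if (y < 2 || re == 0) return(weights)

  others <- ordering[-1]                    # similarity ranks 2..y
  raw <- geometric_pmf(p, seq_len(y - 1))   # nearest neighbour gets pmf(1)
  if (window > 1) {
    blocks <- split(seq_len(y - 1), ceiling(seq_len(y - 1) / window))
    for (b in blocks) {
      if (length(b) > 1) raw[b] <- raw[b][sample.int(length(b))]
    }
  }
  weights[others] <- raw * (re / sum(raw))
  weights
}

#' Blend one cell with its weighted neighbours
#'
#' The SMOTE-style update `a_i* = (1 - RE) * a_i + sum_j f_ij * a_j`: a convex
#' combination of the target cell and every other cell, so non-negativity is
#' preserved and RE = 0 is an exact identity.
#'
#' @param a_i Numeric gene-expression vector of the target cell.
#' @param weights Weight vector from [sample_weights()] (0 at the target's
#'   position).
#' @param matrix The full cells x genes matrix the weights index into.
#' @return The updated cell vector.
#' @export
impute_cell <- function(a_i, weights, matrix) {
  x <- unclass(as_expr_matrix(matrix))
  if (length(weights) != nrow(x)) {
    stop("`weights` length must equal the cell count", call. = FALSE)
  }
  re <- sum(weights)
  drop((1 - re) * a_i + crossprod(weights, x))
}

#' One layer of random imputation
#'
#' Updates every cell synchronously from the pre-layer matrix: sampling each
#' cell's weights from its consensus similarity ordering builds a row-
#' stochastic weight matrix W (diagonal `1 - RE`, off-diagonal the sampled
#' `f_ij`), and the layer output is the matrix product `W %*% A`.
#'
#' @param matrix An [expression_matrix()].
#' @param consensus Consensus similarity matrix from [consensus_matrix()]
#'   (smaller = more similar), or `NULL` to compute it from `matrix` with
#'   default metrics.
#' @inheritParams sample_weights
#' @return The imputed [expression_matrix()], with the weight matrix attached
#'   as attribute `weight_matrix`.
#' @export
impute_layer <- function(matrix, consensus = NULL, p, re = 0.9, window = 4) {
  matrix <- as_expr_matrix(matrix)
  y <- nrow(matrix)
  if (is.null(consensus)) consensus <- consensus_matrix(matrix)
  if (nrow(consensus) != y || ncol(consensus) != y) {
    stop("consensus matrix shape does not match the cell count", call. = FALSE)
  }
  ords <- consensus_orderings(consensus)
  w <- array(0, dim = c(y, y))
  for (i in seq_len(y)) {
    wi <- sample_weights(ords[i, ], p = p, re = re, window = window)
    wi[i] <- 1 - re
    w[i, ] <- wi
  }
  out <- expression_matrix(w %*% unclass(matrix),
                           cell_ids = cell_ids(matrix),
                           gene_ids = gene_ids(matrix))
  attr(out, "weight_matrix") <- w
  out
}
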