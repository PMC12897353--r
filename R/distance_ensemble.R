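#' Pairwise cell-cell dissimilarity
#'
#' Computes a y x y dissimilarity matrix between cell rows under one metric.
#' Correlation metrics (pearson, spearman) return `1 - correlation`; cosine
#' returns `1 - cosine similarity`. A cell whose correlation (or cosine) with
#' another is undefined — a constant expression vector, or an all-zero vector
#' for cosine — gets the maximum dissimilarity 2 for those pairs, with a
#' warning. The diagonal is always exactly 0.
#'
#' @param matrix An [expression_matrix()] (cells x genes), y >= 2.
#' @param metric One of `"euclidean"`, `"pearson"`, `"spearman"`, `"cosine"`.
#' @return A y x y numeric matrix with attribute `metric`.
#' @export
pairwise_distance <- function(matrix,
                              metric = c("euclidean", "pearson", "spearman", "cosine")) {
  metric <- match.arg(metric)
  matrix <- as_expr_matrix(matrix)
  x <- unclass(matrix)
  y <- nrow(x)
  if (y < 2) stop("need at least 2 cells", call. = FALSE)

  d <- switch(metric,
    euclidean = as.matrix(stats::dist(x, method = "euclidean")),
    pearson = cor_dissimilarity(x, method = "pearson"),
    spearman = cor_dissimilarity(x, method = "spearman"),
    cosine = cosine_dissimilarity(x)
  )
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  attr(d, "metric") <- metric
  d
}

cor_dissimilarity <- function(x, method) {
  sds <- apply(x, 1, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  cc <- suppressWarnings(stats::cor(t(x), method = method))
  d <- 1 - cc
  if (any(constant)) {
    warning(sprintf("%d constant cell vector(s); undefined %s correlations set to maximum dissimilarity 2",
                    sum(constant), method))
    d[constant, ] <- 2
    d[, constant] <- 2
  }
  d[!is.finite(d)] <- 2
  d
}

cosine_dissimilarity <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm == 0
  g <- x %*% t(x)
  d <- 1 - g / outer(pmax(nrm, .Machine$double.eps),
                     pmax(nrm, .Machine$double.eps))
  if (any(zero)) {
    warning(sprintf("%d zero cell vector(s); undefined cosine similarities set to maximum dissimilarity 2",
                    sum(zero)))
    d[zero, ] <- 2
    d[, zero] <- 2
  }
  # clip tiny negative values from floating error
  d[d < 0] <- 0
  d
}

#' Convert a distance matrix to a per-row similarity rank matrix
#'
#' Row i orders all cells by ascending dissimilarity to cell i: the cell
#' itself is forced to rank 1, the next most similar cell gets rank 2, and so
#' on. Ties are broken by lower cell index, so every row is a permutation of
#' `1..y`.
#'
#' @param dist A square dissimilarity matrix (e.g. from
#'   [pairwise_distance()]).
#' @return An integer y x y rank matrix.
#' @export
#'
#' @examples
#' d <- rbind(c(0, 5, 2), c(5, 0, 1), c(2, 1, 0))
#' rank_rows(d)
rank_rows <- function(dist) {
  dist <- as.matrix(dist)
  y <- nrow(dist)
  if (y != ncol(dist)) stop("distance matrix must be square", call. = FALSE)
  ranks <- array(0L, dim = dim(dist), dimnames = dimnames(dist))
  for (i in seq_len(y)) {
    d <- dist[i, ]
    d[i] <- -Inf                       # self is most similar by definition
    ord <- order(d, method = "radix")  # stable: ties fall to lower index
    ranks[i, ord] <- seq_len(y)
  }
  ranks
}

#' Aggregate rank matrices into a consensus matrix
#'
#' Elementwise weighted sum `M = sum_n t_n * R_n` of per-metric rank
#' matrices; a smaller consensus value means a more similar cell. With all
#' weights 1 (the default convention) and N metrics every entry lies in
#' `[N, N*y]`.
#'
#' @param ranks List of equally shaped rank matrices.
#' @param weights Numeric vector of per-metric weights `t_n`
#'   (default all 1).
#' @return A numeric y x y matrix with attribute `weights`.
#' @export
aggregate_ranks <- function(ranks, weights = rep(1, length(ranks))) {
  if (!length(ranks)) stop("need at least one rank matrix", call. = FALSE)
  if (length(weights) != length(ranks)) {
    stop("`weights` must have one entry per rank matrix", call. = FALSE)
  }
  dims <- lapply(ranks, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all rank matrices must share the same shape", call. = FALSE)
  }
  m <- array(0, dim = dims[[1]], dimnames = dimnames(ranks[[1]]))
  for (n in seq_along(ranks)) m <- m + weights[n] * ranks[[n]]
  attr(m, "weights") <- weights
  m
}

#' Ensemble consensus similarity matrix
#'
#' Convenience wrapper: computes [pairwise_distance()] under each metric,
#' ranks each with [rank_rows()], and sums the rank matrices with
#' [aggregate_ranks()]. The default ensemble is four standard, complementary
#' metrics, each with weight 1.
#'
#' @inheritParams pairwise_distance
#' @param metrics Character vector of metric names.
#' @param weights Per-metric weights `t_n`.
#' @return The consensus matrix (smaller = more similar).
#' @export
consensus_matrix <- function(matrix,
                             metrics = c("euclidean", "pearson", "spearman", "cosine"),
                             weights = rep(1, length(metrics))) {
  ranks <- lapply(metrics, function(mt) rank_rows(pairwise_distance(matrix, mt)))
  aggregate_ranks(ranks, weights)
}

#' Per-row similarity orderings of a consensus matrix
#'
#' For each cell i, the ordering of all cells by ascending consensus value
#' with the cell itself forced first; ties broken by lower cell index. This is
#' the ordering the imputer's weight sampler consumes.
#'
#' @param consensus A y x y consensus matrix.
#' @return An integer y x y matrix whose row i lists cell indices from most
#'   to least similar to cell i (row i starts with i).
#' @export
consensus_orderings <- function(consensus) {
  y <- nrow(consensus)
  out <- array(0L, dim = c(y, y))
  for (i in seq_len(y)) {
    v <- consensus[i, ]
    v[i] <- -Inf
    out[i, ] <- order(v, method = "radix")
  }
  out
}
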