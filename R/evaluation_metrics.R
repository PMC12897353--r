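#' Seeded k-means clustering of cells
#'
#' Thin front end over [stats::kmeans()]: best of `n_restarts` random starts
#' by within-cluster sum of squares, reproducible given `seed`. Cluster ids
#' are returned in R's 1..k convention.
#'
#' @param matrix Numeric matrix, rows = cells (e.g. a low-dimensional
#'   representation or an imputed expression matrix).
#' @param k Number of clusters (`1 <= k <=` number of cells).
#' @param seed Integer seed.
#' @param n_restarts Number of random restarts (default 10).
#' @return An object of class `scirt_clustering`: list with `assignments`
#'   (integer vector in 1..k), `k`, `inertia` (total within-cluster sum of
#'   squares).
#' @export
kmeans_cluster <- function(matrix, k, seed = 1, n_restarts = 10) {
  x <- unclass(as.matrix(matrix))
  if (k < 1 || k != round(k)) stop("`k` must be a positive integer", call. = FALSE)
  if (k > nrow(x)) stop("`k` cannot exceed the number of cells", call. = FALSE)
  set.seed(as.integer(seed))
  fit <- suppressWarnings(
    stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 100)
  )
  structure(
    list(assignments = as.integer(fit$cluster), k = as.integer(k),
         inertia = fit$tot.withinss),
    class = "scirt_clustering"
  )
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two labelings with the expected-index
#' correction: 1 for identical partitions, ~0 for independent ones (an
#' all-in-one-cluster labeling scores exactly 0 against any non-trivial
#' one). Symmetric and invariant to label permutation.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type).
#' @return A scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  check_equal_length(labels_a, labels_b)
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information
#'
#' Mutual information of two labelings normalized by a summary of their
#' entropies (arithmetic mean by default; min, geometric and max variants
#' available). 1 for identical partitions, near 0 for independent ones;
#' `0 * log 0` is taken as 0 throughout.
#'
#' @inheritParams adjusted_rand_index
#' @param variant Entropy normalization: `"arithmetic"` (default), `"min"`,
#'   `"geometric"` or `"max"`.
#' @return A scalar in \[0, 1\].
#' @export
normalized_mutual_information <- function(labels_a, labels_b,
                                          variant = c("arithmetic", "min", "geometric", "max")) {
  variant <- match.arg(variant)
  check_equal_length(labels_a, labels_b)
  n <- length(labels_a)
  joint <- table(labels_a, labels_b) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  outer_p <- outer(pa, pb)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer_p[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  denom <- switch(variant,
    arithmetic = (ha + hb) / 2,
    min = min(ha, hb),
    geometric = sqrt(ha * hb),
    max = max(ha, hb)
  )
  if (denom == 0) return(if (mi == 0) 1 else 0)  # both partitions trivial
  max(0, min(1, mi / denom))
}

#' Silhouette coefficient
#'
#' Mean over cells of `(b - a) / max(a, b)` where `a` is the mean euclidean
#' distance to the cell's own cluster and `b` the smallest mean distance to
#' another cluster. Cells in singleton clusters get silhouette 0 (with a
#' warning). Higher is better; range \[-1, 1\].
#'
#' @param matrix Numeric matrix, rows = cells.
#' @param assignments Cluster label per cell (>= 2 distinct, all non-empty).
#' @return The mean silhouette width.
#' @export
silhouette_coefficient <- function(matrix, assignments) {
  x <- unclass(as.matrix(matrix))
  check_equal_length(seq_len(nrow(x)), assignments)
  cl <- as.integer(factor(assignments))
  if (length(unique(cl)) < 2) stop("need >= 2 clusters", call. = FALSE)
  d <- as.matrix(stats::dist(x))
  sizes <- tabulate(cl)
  if (any(sizes[unique(cl)] == 1)) {
    warning("singleton cluster(s): their cells get silhouette 0")
  }
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- cl[i]
    if (sizes[own] == 1) return(0)
    a <- sum(d[i, cl == own]) / (sizes[own] - 1)   # exclude self
    b <- min(vapply(setdiff(unique(cl), own),
                    function(g) mean(d[i, cl == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case ratio
#' `(s_i + s_j) / d_ij`, with `s` the mean euclidean distance of a cluster's
#' cells to their centroid and `d_ij` the centroid separation. Lower is
#' better; coincident centroids are guarded by a small epsilon (with a
#' warning).
#'
#' @inheritParams silhouette_coefficient
#' @return A non-negative scalar.
#' @export
davies_bouldin_index <- function(matrix, assignments) {
  x <- unclass(as.matrix(matrix))
  check_equal_length(seq_len(nrow(x)), assignments)
  cl <- as.integer(factor(assignments))
  ks <- sort(unique(cl))
  if (length(ks) < 2) stop("need >= 2 clusters", call. = FALSE)
  centroids <- t(vapply(ks, function(g) colMeans(x[cl == g, , drop = FALSE]),
                        numeric(ncol(x))))
  scatter <- vapply(seq_along(ks), function(gi) {
    pts <- x[cl == ks[gi], , drop = FALSE]
    mean(sqrt(rowSums((pts - rep(centroids[gi, ], each = nrow(pts)))^2)))
  }, numeric(1))
  sep <- as.matrix(stats::dist(centroids))
  if (any(sep[upper.tri(sep)] < .Machine$double.eps)) {
    warning("coincident centroids: separation floored at machine epsilon")
    sep[sep < .Machine$double.eps] <- .Machine$double.eps
  }
  mean(vapply(seq_along(ks), function(i) {
    max(vapply(setdiff(seq_along(ks), i),
               function(j) (scatter[i] + scatter[j]) / sep[i, j], numeric(1)))
  }, numeric(1)))
}

#' Flattened-matrix Pearson correlation
#'
#' Pearson correlation of two equally shaped matrices flattened to vectors:
#' a structural-similarity score between, e.g., a raw and an imputed
#' expression matrix. 1 for any positive affine transform of the same
#' matrix.
#'
#' @param matrix_a,matrix_b Numeric matrices of identical shape, at least
#'   one value pattern non-constant in each.
#' @return A scalar in \[-1, 1\].
#' @export
corr2 <- function(matrix_a, matrix_b) {
  a <- unclass(as.matrix(matrix_a))
  b <- unclass(as.matrix(matrix_b))
  if (!identical(dim(a), dim(b))) stop("matrices must have identical shapes", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: constant matrix", call. = FALSE)
  }
  stats::cor(as.vector(a), as.vector(b))
}

check_equal_length <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("length mismatch: %d vs %d", length(a), length(b)), call. = FALSE)
  }
  invisible(TRUE)
}
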