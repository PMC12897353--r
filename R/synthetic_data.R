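#' Simulate a cluster-structured scRNA-seq count matrix
#'
#' Generates a negative-binomial count matrix with known cell-type labels, the
#' test bed for the whole imputation pipeline. Each gene gets a lognormal
#' baseline mean centred on `base_mean`; each cluster independently draws
#' `de_fraction` of the genes as differentially expressed and multiplies
#' their means by `effect_size`; counts are NB with shape `dispersion`.
#' Cells are assigned to clusters as evenly as possible.
#'
#' Defaults correspond to the package's reference benchmark: 300 cells x
#' 500 genes in 3 clusters with an 8-fold shift on 20% of genes.
#'
#' @param n_cells,n_genes,n_clusters Matrix dimensions and number of cell
#'   types (`n_clusters <= n_cells`).
#' @param de_fraction Fraction of genes differentially expressed per cluster,
#'   in \[0, 1\].
#' @param effect_size Multiplicative mean shift for DE genes (> 1; exactly 1
#'   produces a label-free null model).
#' @param base_mean Median baseline expression mean (counts).
#' @param dispersion Negative-binomial shape (`size`); smaller = more
#'   overdispersed.
#' @param seed Integer seed; the draw is bit-reproducible given the seed.
#' @return A list with `matrix` (an [expression_matrix()] of counts) and
#'   `labels` (character vector `type_1..type_k`, one per cell).
#' @export
#'
#' @examples
#' sim <- simulate_counts(n_cells = 30, n_genes = 40, n_clusters = 2, seed = 1)
#' table(sim$labels)
simulate_counts <- function(n_cells = 300, n_genes = 500, n_clusters = 3,
                            de_fraction = 0.2, effect_size = 8,
                            base_mean = 2, dispersion = 2, seed = 1) {
  stopifnot(n_cells >= 1, n_genes >= 1)
  if (n_clusters < 1 || n_clusters > n_cells) {
    stop("`n_clusters` must be in [1, n_cells]", call. = FALSE)
  }
  if (de_fraction < 0 || de_fraction > 1) {
    stop("`de_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (effect_size < 1) stop("`effect_size` must be >= 1", call. = FALSE)
  if (base_mean <= 0 || dispersion <= 0) {
    stop("`base_mean` and `dispersion` must be positive", call. = FALSE)
  }

  set.seed(as.integer(seed))
  base_mu <- stats::rlnorm(n_genes, meanlog = log(base_mean), sdlog = 0.5)
  n_de <- round(de_fraction * n_genes)
  labels_int <- sort(rep_len(seq_len(n_clusters), n_cells))

  mu_by_cluster <- matrix(rep(base_mu, each = n_clusters),
                          nrow = n_clusters, ncol = n_genes)
  for (cl in seq_len(n_clusters)) {
    if (n_de > 0) {
      de_genes <- sample.int(n_genes, n_de)
      mu_by_cluster[cl, de_genes] <- mu_by_cluster[cl, de_genes] * effect_size
    }
  }

  counts <- matrix(0, n_cells, n_genes)
  for (cl in seq_len(n_clusters)) {
    idx <- which(labels_int == cl)
    counts[idx, ] <- matrix(
      stats::rnbinom(length(idx) * n_genes, size = dispersion,
                     mu = rep(mu_by_cluster[cl, ], each = length(idx))),
      nrow = length(idx)
    )
  }

  list(
    matrix = expression_matrix(counts),
    labels = paste0("type_", labels_int)
  )
}

#' Mask matrix entries to emulate dropout
#'
#' Zeroes exactly `round(rate * n_cells * n_genes)` entries chosen uniformly
#' at random without replacement over all matrix elements — entries already
#' zero may be selected (a value no-op, still recorded in the mask). With
#' `nonzero_only = TRUE` the draw is restricted to currently nonzero entries
#' (clamped to their count).
#'
#' @param matrix An [expression_matrix()].
#' @param rate Fraction of elements to zero, in \[0, 1\].
#' @param seed Integer seed; mask positions are seed-reproducible.
#' @param nonzero_only Restrict masking to nonzero entries.
#' @return A list with `matrix` (masked copy) and `mask` (logical matrix,
#'   `TRUE` at zeroed positions).
#' @export
#'
#' @examples
#' m <- expression_matrix(matrix(1:20, 4, 5))
#' out <- apply_dropout(m, rate = 0.25, seed = 7)
#' sum(out$mask)  # exactly round(0.25 * 20) = 5
apply_dropout <- function(matrix, rate, seed = 1, nonzero_only = FALSE) {
  matrix <- as_expr_matrix(matrix)
  if (length(rate) != 1 || !is.finite(rate) || rate < 0 || rate > 1) {
    stop("`rate` must be a fraction in [0, 1]", call. = FALSE)
  }
  n <- length(matrix)
  n_mask <- round(rate * n)
  set.seed(as.integer(seed))
  pool <- if (nonzero_only) which(unclass(matrix) != 0) else seq_len(n)
  n_mask <- min(n_mask, length(pool))
  idx <- if (n_mask > 0) pool[sample.int(length(pool), n_mask)] else integer(0)
  mask <- array(FALSE, dim = dim(matrix), dimnames = dimnames(matrix))
  mask[idx] <- TRUE
  out <- matrix
  out[idx] <- 0
  list(matrix = out, mask = mask)
}
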