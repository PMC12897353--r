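#' Build the multi-layer imputation schedule
#'
#' The number of layers is `mean_number = floor(log2(y / nc))`: each layer
#' doubles the expected number of neighbours contributing weight mass
#' (`times = 2, 4, ..., 2^mean_number`), stopping once a layer would span the
#' shrunken expected cluster size `eec = floor(y / nc * shrink)`. Layer l
#' uses geometric parameter `p = 1 / times[l]`; the top layer instead uses
#' the flat curve `p = nc / y`, spreading weight nearly evenly over all
#' similar cells.
#'
#' @param y Number of cells.
#' @param nc Number of expected cell types (`1 <= nc < y`, and
#'   `y / nc >= 2` so at least one layer exists).
#' @param shrink Shrinkage coefficient in (0, 1] applied to the expected
#'   cluster size (default 0.9).
#' @return An object of class `scirt_schedule`: a list with `mean_number`,
#'   `times`, `eec`, `p_schedule`, `shrink`, `y`, `nc`.
#' @export
#'
#' @examples
#' build_schedule(430, 5)  # 6 layers, eec = 77
build_schedule <- function(y, nc, shrink = 0.9) {
  stopifnot(length(y) == 1, length(nc) == 1)
  if (nc < 1) stop("`nc` must be >= 1", call. = FALSE)
  if (y <= nc) stop("`y` must exceed `nc`: no layering possible", call. = FALSE)
  if (shrink <= 0 || shrink > 1) stop("`shrink` must be in (0, 1]", call. = FALSE)
  mean_number <- floor(log2(y / nc))
  if (mean_number < 1) {
    stop("floor(log2(y / nc)) < 1: no layering possible", call. = FALSE)
  }
  times <- 2^(seq_len(mean_number))
  eec <- floor(y / nc * shrink)
  p_schedule <- ifelse(times <= eec, 1 / times, nc / y)
  p_schedule[mean_number] <- nc / y   # flat top layer
  structure(
    list(mean_number = mean_number, times = times, eec = eec,
         p_schedule = p_schedule, shrink = shrink, y = y, nc = nc),
    class = "scirt_schedule"
  )
}

#' @export
print.scirt_schedule <- function(x, ...) {
  cat(sprintf("<scirt_schedule> %d layer(s) for %d cells / %d types (eec = %d)\n",
              x$mean_number, x$y, x$nc, x$eec))
  cat("  times:", paste(x$times, collapse = " "), "\n")
  cat("  p:    ", paste(signif(x$p_schedule, 4), collapse = " "), "\n")
  invisible(x)
}

#' Run the full iterative imputation pipeline
#'
#' For each layer of the schedule: (a) the consensus similarity matrix is
#' recomputed on the current working matrix (unless `freeze_ranks = TRUE`,
#' which keeps the consensus from the raw input), (b) every cell is blended
#' with randomly weighted similar cells ([impute_layer()]) using that layer's
#' geometric parameter, and (c) the imputed matrix is replaced by its rank-k
#' NMF reconstruction, recording the RMS residual between the imputed and
#' reconstructed matrices. After the last layer one final factorization
#' yields the imputed high-dimensional matrix (`Z %*% H`, cells x genes) and
#' the low-dimensional cell representation (`Z`, cells x k) used for
#' clustering.
#'
#' @param matrix An [expression_matrix()] (cells x genes, non-negative).
#' @param nc Number of expected cell types (supplied by the user, as in
#'   standard practice; >= 2 recommended).
#' @param k Factorization rank for the per-layer and final NMF (defaults to
#'   `nc`).
#' @param re Total external weight mass RE in \[0, 1\] (default 0.9).
#' @param shrink Cluster-size shrinkage coefficient (default 0.9; a distinct
#'   parameter from `re` that happens to share its default).
#' @param window Local-shuffle block size for weight sampling (default 4).
#' @param metrics,weights Distance ensemble configuration (see
#'   [consensus_matrix()]).
#' @param noise_model NMF noise model, `"gaussian"` or `"poisson"`.
#' @param max_iter,tol NMF stopping controls per factorization.
#' @param seed Master seed; the whole run is deterministic given it.
#' @param freeze_ranks Keep the consensus matrix computed on the input
#'   instead of recomputing per layer.
#' @param keep_layers Also return the working matrix after each layer's
#'   reconstruction (as `layer_matrices`), for inspecting how cluster
#'   structure sharpens across layers.
#' @return An object of class `scirt_result`: a list with `high_dim`
#'   (imputed cells x genes [expression_matrix()]), `low_dim` (cells x k
#'   matrix), `per_layer_rms`, `schedule`, `final_fit` (the last `scirt_nmf`),
#'   and `config`.
#' @export
#'
#' @examples
#' sim <- simulate_counts(n_cells = 40, n_genes = 60, n_clusters = 2, seed = 1)
#' res <- run_scirt(sim$matrix, nc = 2, seed = 1)
#' dim(res$low_dim)
run_scirt <- function(matrix, nc, k = nc, re = 0.9, shrink = 0.9, window = 4,
                      metrics = c("euclidean", "pearson", "spearman", "cosine"),
                      weights = rep(1, length(metrics)),
                      noise_model = c("gaussian", "poisson"),
                      max_iter = 200, tol = 1e-4,
                      seed = NULL, freeze_ranks = FALSE, keep_layers = FALSE) {
  noise_model <- match.arg(noise_model)
  matrix <- as_expr_matrix(matrix)
  if (!is.null(seed)) set.seed(as.integer(seed))
  y <- n_cells(matrix)
  schedule <- build_schedule(y, nc, shrink)

  config <- list(nc = nc, k = k, re = re, shrink = shrink, window = window,
                 metrics = metrics, weights = weights,
                 noise_model = noise_model, max_iter = max_iter, tol = tol,
                 seed = seed, freeze_ranks = freeze_ranks)

  a <- matrix
  consensus <- if (freeze_ranks) consensus_matrix(a, metrics, weights) else NULL
  per_layer_rms <- numeric(schedule$mean_number)
  layer_matrices <- if (keep_layers) vector("list", schedule$mean_number) else NULL

  for (l in seq_len(schedule$mean_number)) {
    cm <- if (freeze_ranks) consensus else consensus_matrix(a, metrics, weights)
    imputed <- impute_layer(a, cm, p = schedule$p_schedule[l],
                            re = re, window = window)
    fit <- nmf_factorize(imputed, k = k, noise_model = noise_model,
                         max_iter = max_iter, tol = tol)
    recon <- reconstruct(fit)
    if (any(!is.finite(recon))) {
      stop(sprintf("non-finite values after NMF reconstruction at layer %d", l),
           call. = FALSE)
    }
    per_layer_rms[l] <- sqrt(mean((unclass(imputed) - recon)^2))
    a <- expression_matrix(recon, cell_ids = cell_ids(matrix),
                           gene_ids = gene_ids(matrix))
    if (keep_layers) layer_matrices[[l]] <- a
  }

  final_fit <- nmf_factorize(a, k = k, noise_model = noise_model,
                             max_iter = max_iter, tol = tol)
  high_dim <- expression_matrix(reconstruct(final_fit),
                                cell_ids = cell_ids(matrix),
                                gene_ids = gene_ids(matrix))
  low_dim <- final_fit$Z
  rownames(low_dim) <- cell_ids(matrix)

  structure(
    list(high_dim = high_dim, low_dim = low_dim,
         per_layer_rms = per_layer_rms, schedule = schedule,
         final_fit = final_fit, config = config,
         layer_matrices = layer_matrices),
    class = "scirt_result"
  )
}

#' @export
print.scirt_result <- function(x, ...) {
  cat(sprintf("<scirt_result> %d cells x %d genes imputed; low-dim rank %d\n",
              nrow(x$high_dim), ncol(x$high_dim), ncol(x$low_dim)))
  cat(sprintf("  %d layer(s); per-layer RMS residual: %s\n",
              x$schedule$mean_number,
              paste(signif(x$per_layer_rms, 4), collapse = " ")))
  invisible(x)
}
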