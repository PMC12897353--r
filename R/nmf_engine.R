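#' NMF objective functions
#'
#' `objective_euclidean` is the squared Frobenius norm of the residual,
#' `sum((A - ZH)^2)`; `objective_kl` is the generalized Kullback-Leibler
#' divergence `sum(A * log(A / ZH) - A + ZH)` with the `0 * log 0 = 0`
#' convention and epsilon-guarded denominators.
#'
#' @param A Non-negative target matrix (u x v).
#' @param Z Non-negative u x k factor.
#' @param H Non-negative k x v factor.
#' @param eps Underflow guard for the KL denominator.
#' @return A non-negative scalar (0 at an exact factorization).
#' @export
objective_euclidean <- function(A, Z, H) {
  sum((A - Z %*% H)^2)
}

#' @rdname objective_euclidean
#' @export
objective_kl <- function(A, Z, H, eps = 1e-12) {
  zh <- Z %*% H
  pos <- A > 0
  val <- sum(zh) - sum(A)
  if (any(pos)) {
    val <- val + sum(A[pos] * log(A[pos] / pmax(zh[pos], eps)))
  }
  val
}

#' Lee-Seung multiplicative updates
#'
#' One paired update of both factors. `update_gaussian` implements the
#' Frobenius rules `Z <- Z * (A H') / (Z H H')` then
#' `H <- H * (Z' A) / (Z' Z H)` (with the already-updated Z); `update_poisson`
#' the KL rules `Z_uk <- Z_uk * (sum_v H_kv A_uv / (ZH)_uv) / sum_v H_kv` and
#' the symmetric H rule. Denominators are floored at `eps` so the update is
#' defined everywhere; both rules preserve non-negativity and never increase
#' the matching objective.
#'
#' @inheritParams objective_euclidean
#' @return A list with updated `Z` and `H`.
#' @export
update_gaussian <- function(A, Z, H, eps = 1e-12) {
  Z <- Z * (A %*% t(H)) / pmax(Z %*% (H %*% t(H)), eps)
  H <- H * (t(Z) %*% A) / pmax((t(Z) %*% Z) %*% H, eps)
  list(Z = Z, H = H)
}

#' @rdname update_gaussian
#' @export
update_poisson <- function(A, Z, H, eps = 1e-12) {
  R <- A / pmax(Z %*% H, eps)
  Z <- Z * (R %*% t(H)) / pmax(matrix(rowSums(H), nrow(Z), nrow(H), byrow = TRUE), eps)
  R <- A / pmax(Z %*% H, eps)
  H <- H * (t(Z) %*% R) / pmax(matrix(colSums(Z), ncol(Z), ncol(H)), eps)
  list(Z = Z, H = H)
}

#' Non-negative matrix factorization
#'
#' Factorizes a non-negative matrix as `A ~ Z %*% H` with `Z` (u x k) and `H`
#' (k x v) elementwise non-negative, by iterating the Lee-Seung
#' multiplicative update for the chosen noise model from a seeded
#' uniform(0, 1) initialization scaled by `sqrt(mean(A) / k)`. Iteration
#' stops when the relative objective change drops below `tol` or after
#' `max_iter` paired updates; the per-iteration objective is recorded in
#' `objective_trace` (non-increasing by construction). An all-zero input
#' returns zero factors immediately.
#'
#' @param A Non-negative numeric matrix (an [expression_matrix()] or plain
#'   matrix).
#' @param k Target rank (a warning is issued if `k > min(dim(A))`).
#' @param noise_model `"gaussian"` (Frobenius objective) or `"poisson"`
#'   (generalized KL objective, natural for counts).
#' @param max_iter Maximum number of paired updates.
#' @param tol Relative objective-change stopping threshold.
#' @param eps Underflow guard; factor entries are floored here so
#'   multiplicative updates cannot get stuck at exact zero.
#' @param seed Optional integer seed for the initialization; `NULL` uses the
#'   current RNG state.
#' @return An object of class `scirt_nmf`: a list with `Z`, `H`, `k`,
#'   `noise_model`, `objective_trace`, `iterations`, `converged`.
#' @export
#'
#' @examples
#' fit <- nmf_factorize(rbind(c(1, 2), c(2, 4)), k = 1, seed = 1)
#' tail(fit$objective_trace, 1)  # ~0: the matrix is exactly rank 1
nmf_factorize <- function(A, k,
                          noise_model = c("gaussian", "poisson"),
                          max_iter = 200, tol = 1e-4, eps = 1e-12,
                          seed = NULL) {
  noise_model <- match.arg(noise_model)
  A <- unclass(as.matrix(A))
  if (any(A < 0) || any(!is.finite(A))) {
    stop("`A` must be finite and non-negative", call. = FALSE)
  }
  if (k < 1 || k != round(k)) stop("`k` must be a positive integer", call. = FALSE)
  u <- nrow(A); v <- ncol(A)
  if (k > min(u, v)) warning("rank k exceeds min(dim(A)); factorization is overcomplete")
  if (!is.null(seed)) set.seed(as.integer(seed))

  new_fit <- function(Z, H, trace, converged) {
    structure(
      list(Z = Z, H = H, k = as.integer(k), noise_model = noise_model,
           objective_trace = trace, iterations = length(trace),
           converged = converged),
      class = "scirt_nmf"
    )
  }

  if (all(A == 0)) {
    return(new_fit(matrix(0, u, k), matrix(0, k, v), trace = 0, converged = TRUE))
  }

  scale <- sqrt(mean(A) / k)
  Z <- matrix(stats::runif(u * k), u, k) * scale
  H <- matrix(stats::runif(k * v), k, v) * scale
  objective <- if (noise_model == "gaussian") objective_euclidean else objective_kl
  update <- if (noise_model == "gaussian") update_gaussian else update_poisson

  trace <- numeric(max_iter)
  prev <- objective(A, Z, H)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    upd <- update(A, Z, H, eps = eps)
    Z <- pmax(upd$Z, eps)
    H <- pmax(upd$H, eps)
    obj <- objective(A, Z, H)
    trace[it] <- obj
    if (is.finite(prev) && abs(prev - obj) <= tol * max(abs(prev), eps)) {
      converged <- TRUE
      break
    }
    prev <- obj
  }
  new_fit(Z, H, trace = trace[seq_len(it)], converged = converged)
}

#' Reconstruction from a factorization
#'
#' @param object A `scirt_nmf` fit.
#' @return The non-negative reconstruction `Z %*% H`.
#' @export
reconstruct <- function(object) {
  stopifnot(inherits(object, "scirt_nmf"))
  object$Z %*% object$H
}

#' @export
print.scirt_nmf <- function(x, ...) {
  cat(sprintf("<scirt_nmf> rank %d, %s noise, %d iteration(s), final objective %.6g%s\n",
              x$k, x$noise_model, x$iterations,
              tail_or_na(x$objective_trace),
              if (x$converged) "" else " (max_iter reached)"))
  invisible(x)
}

tail_or_na <- function(v) if (length(v)) v[length(v)] else NA_real_
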