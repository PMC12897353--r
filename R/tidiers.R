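#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an NMF fit
#'
#' @param x A `scirt_nmf` object.
#' @param ... Unused.
#' @return A tibble with one row per iteration: `iteration`, `objective`.
#' @export
tidy.scirt_nmf <- function(x, ...) {
  tibble::tibble(
    iteration = seq_along(x$objective_trace),
    objective = x$objective_trace
  )
}

#' @rdname tidy.scirt_nmf
#' @export
glance.scirt_nmf <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    noise_model = x$noise_model,
    iterations = x$iterations,
    converged = x$converged,
    final_objective = tail_or_na(x$objective_trace)
  )
}

#' Tidy a pipeline result
#'
#' @param x A `scirt_result` object.
#' @param ... Unused.
#' @return A tibble with one row per layer: `layer`, `times`
#'   (expected contributing neighbours), `p` (geometric parameter),
#'   `rms_residual` (imputed vs NMF-reconstructed).
#' @export
tidy.scirt_result <- function(x, ...) {
  tibble::tibble(
    layer = seq_len(x$schedule$mean_number),
    times = x$schedule$times,
    p = x$schedule$p_schedule,
    rms_residual = x$per_layer_rms
  )
}

#' @rdname tidy.scirt_result
#' @export
glance.scirt_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$high_dim),
    n_genes = ncol(x$high_dim),
    n_layers = x$schedule$mean_number,
    k = ncol(x$low_dim),
    eec = x$schedule$eec,
    final_objective = tail_or_na(x$final_fit$objective_trace)
  )
}

#' Plot methods
#'
#' `autoplot.scirt_nmf` draws the objective trace; `autoplot.scirt_result`
#' draws the per-layer RMS residual between each layer's imputed matrix and
#' its NMF reconstruction. Both require ggplot2.
#'
#' @param object Fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scirt_nmf <- function(object, ...) {
  require_ggplot2()
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$iteration, .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "iteration", y = "objective (log scale)",
      title = sprintf("NMF descent (rank %d, %s noise)", object$k, object$noise_model)
    )
}

#' @rdname autoplot.scirt_nmf
#' @exportS3Method ggplot2::autoplot
autoplot.scirt_result <- function(object, ...) {
  require_ggplot2()
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$layer, .data$rms_residual)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "layer", y = "RMS residual (imputed vs reconstruction)",
                  title = "Per-layer reconstruction residual")
}

require_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for autoplot()", call. = FALSE)
  }
}

#' @importFrom rlang .data
NULL
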