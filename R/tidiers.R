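#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and summarize a training fit
#'
#' `tidy()` returns the per-learning-step log (one row per step, module and
#' readout: mean absolute error, RMS error, weight norm, and the windowed
#' chunk correlations when available). `glance()` returns a one-row summary
#' with the final-step mean absolute error and the best final-step chunk
#' correlation.
#'
#' @param x A `dualrc_fit` from [train_dual()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dualrc_fit <- function(x, ...) {
  log <- x$log
  if (!is.null(x$correlations) && nrow(x$correlations)) {
    best <- dplyr::summarise(
      dplyr::group_by(x$correlations, .data$step, .data$module, .data$readout),
      best_correlation = max(.data$correlation), .groups = "drop")
    log <- dplyr::left_join(log, best, by = c("step", "module", "readout"))
  }
  log
}

#' @rdname tidy.dualrc_fit
#' @export
glance.dualrc_fit <- function(x, ...) {
  n_steps <- max(x$log$step)
  final <- dplyr::filter(x$log, .data$step == n_steps)
  out <- tibble(n_steps = n_steps,
                final_mae = mean(final$mae),
                final_w_norm = mean(final$w_norm))
  if (!is.null(x$correlations) && nrow(x$correlations)) {
    fc <- dplyr::filter(x$correlations, .data$step == n_steps)
    out$final_correlation <- max(fc$correlation)
  }
  out
}

#' @rdname tidy.dualrc_fit
#' @export
tidy.dualrc_eval <- function(x, ...) x$z

#' @rdname tidy.dualrc_fit
#' @export
glance.dualrc_eval <- function(x, ...) {
  out <- tibble(n_samples = nrow(x$z1), n_readouts = ncol(x$z1))
  if (!is.null(x$correlations))
    out$best_correlation <- max(x$correlations$correlation)
  out
}

#' Plot training progress
#'
#' Mean absolute error and readout weight norm per learning step, one facet
#' per quantity, colored by module.
#'
#' @param object A `dualrc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dualrc_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("mae", "w_norm"),
                            names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$value,
                                   colour = factor(.data$module),
                                   group = interaction(.data$module,
                                                       .data$readout))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "learning step (15 s each)", y = NULL,
                  colour = "module")
}

#' Plot evaluated readout traces
#'
#' Readout outputs against time, one facet per module, with chunk presentation
#' windows shaded when a stream is supplied.
#'
#' @param object A `dualrc_eval`.
#' @param stream Optional [symbol_stream()] for chunk shading.
#' @param max_ms Truncate the display after this many ms (default 15000).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dualrc_eval <- function(object, stream = NULL, max_ms = 15000, ...) {
  df <- dplyr::filter(object$z, .data$time_ms < max_ms)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$z,
                                        colour = factor(.data$readout))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~module, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (ms)", y = "readout output z",
                  colour = "readout")
  if (!is.null(stream)) {
    cw <- chunk_windows(stream, object$symbol_ms)
    cw <- dplyr::filter(cw, .data$start_ms < max_ms)
    p <- p + ggplot2::geom_rect(
      data = cw, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = -Inf, ymax = Inf, fill = factor(.data$chunk)),
      alpha = 0.15) +
      ggplot2::labs(fill = "chunk")
  }
  p
}

#' Plot principal-component diagnostics
#'
#' Eigenvalue spectrum (log scale) and the within-self / between-partner
#' reconstruction-error curves against the subspace dimension.
#'
#' @param object A `pca_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_report <- function(object, ...) {
  curves <- tidyr::pivot_longer(object$curves, c("e_within", "e_between"),
                                names_to = "comparison", values_to = "error")
  curves <- dplyr::filter(curves, !is.na(.data$error))
  ggplot2::ggplot(curves, ggplot2::aes(.data$M, .data$error,
                                       colour = .data$comparison)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "subspace dimension M",
                  y = "mean squared reconstruction error")
}

#' Plot a trial-averaged response profile
#'
#' @param object A `trial_average`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trial_average <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$lag_ms, .data$value,
                               group = .data$unit)) +
    ggplot2::geom_line(alpha = if (ncol(object$mean) > 5) 0.3 else 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time from chunk onset (ms)", y = "mean response")
}
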