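#' Plot mean test error against the number of boosting iterations
#'
#' @param object An `hdb_experiment` from [run_experiment()].
#' @param metric Summary column to plot (default `"test_error_mean"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hdb_experiment <- function(object, metric = "test_error_mean",
                                    ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$m, y = .data[[metric]],
                               colour = .data$classifier)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "boosting iterations (M)", y = metric,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validated iteration-selection curve
#'
#' @param object An `hdb_cv` from [select_m_by_cv()].
#' @param ... Unused.
#' @return A ggplot object with the selected iteration count marked.
#' @export
autoplot.hdb_cv <- function(object, ...) {
  ggplot2::ggplot(object$cv_curve,
                  ggplot2::aes(x = .data$m, y = .data$cv_error)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$m_cv, linetype = "dashed") +
    ggplot2::labs(x = "boosting iterations (M)",
                  y = "cross-validated error",
                  subtitle = sprintf("selected M = %d", object$m_cv)) +
    ggplot2::theme_minimal()
}

#' Plot staged test-error curves for one or more fitted ensembles
#'
#' @param curves A tibble from [staged_errors()], or a named list of them
#'   (names become the legend).
#' @return A ggplot object.
#' @export
plot_staged_errors <- function(curves) {
  if (is.data.frame(curves)) curves <- list(model = curves)
  df <- purrr::list_rbind(purrr::imap(curves, function(d, nm) {
    d$classifier <- nm
    d
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$error,
                                   colour = .data$classifier)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "boosting iterations (M)", y = "test error",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
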