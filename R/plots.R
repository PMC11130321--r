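#' Plot methods
#'
#' `autoplot()` methods for the package's result types, all returning
#' ggplot objects: traces as signal-versus-time lines, axon profiles as
#' intensity-versus-depth with layer boundaries, cross-validation results
#' as the accuracy distribution, and input matrices as layer-by-cell-type
#' heat maps (via [plot_input_matrix()]).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name circuitmapr-plots
NULL

#' @rdname circuitmapr-plots
#' @export
autoplot.vc_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(as.data.frame(object)),
                  ggplot2::aes(x = .data$time_ms, y = .data$current_pa)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (ms)", y = "Current (pA)") +
    ggplot2::theme_minimal()
}

#' @rdname circuitmapr-plots
#' @export
autoplot.cc_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(as.data.frame(object)),
                  ggplot2::aes(x = .data$time_ms, y = .data$voltage_mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (ms)", y = "Voltage (mV)") +
    ggplot2::theme_minimal()
}

#' @rdname circuitmapr-plots
#' @export
autoplot.axon_profile <- function(object, ...) {
  table <- attr(object, "layer_table") %||% layer_table()
  ggplot2::ggplot(as_tibble(as.data.frame(object)),
                  ggplot2::aes(x = .data$depth_um, y = .data$intensity_au)) +
    ggplot2::geom_vline(xintercept = table$lower_um, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "Depth from pia (µm)", y = "Intensity (AU)") +
    ggplot2::theme_minimal()
}

#' @rdname circuitmapr-plots
#' @param null An optional `ih_null` whose 95% interval is drawn behind
#'   the per-repeat accuracies.
#' @export
autoplot.ih_cv <- function(object, null = NULL, ...) {
  p <- ggplot2::ggplot(object$per_repeat,
                       ggplot2::aes(x = .data$repeat_, y = .data$accuracy))
  if (!is.null(null)) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = null$interval_95[1],
                               ymax = null$interval_95[2],
                               alpha = 0.2, fill = "grey50")
  }
  p +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, colour = "red") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Repeat", y = "Cross-validated accuracy") +
    ggplot2::theme_minimal()
}

#' @rdname circuitmapr-plots
#' @param matrix An input matrix from [assemble_input_matrix()].
#' @param fill Which column to map to fill (`"mean_amplitude_mv"` or
#'   `"normalized_amplitude"`).
#' @export
plot_input_matrix <- function(matrix, fill = "mean_amplitude_mv") {
  ggplot2::ggplot(matrix,
                  ggplot2::aes(x = .data$cell_class, y = .data$layer,
                               fill = .data[[fill]])) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(layer_table()$layer)) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = fill) +
    ggplot2::theme_minimal()
}
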