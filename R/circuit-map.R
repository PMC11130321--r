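#' Cortical layer boundaries
#'
#' Depth intervals (µm from the pial surface) for layers L1–L6, as
#' half-open intervals `[upper, lower)`. The defaults are a documented
#' mouse-V1 convention; real analyses should substitute atlas-derived
#' boundaries for their sections.
#'
#' @param boundaries Increasing depths (µm) of the five layer floors, i.e.
#'   the lower bounds of L1, L2/3, L4, L5, L6.
#' @return A tibble (`layer`, `upper_um`, `lower_um`) of class
#'   `layer_table`.
#' @examples
#' layer_table()
#' assign_layer(c(50, 430, 849))
#' @export
layer_table <- function(boundaries = c(100, 310, 430, 600, 850)) {
  if (length(boundaries) != 5L || is.unsorted(boundaries, strictly = TRUE) ||
      boundaries[1] <= 0) {
    abort("`boundaries` must be five strictly increasing positive depths.")
  }
  out <- tibble(
    layer = c("L1", "L2/3", "L4", "L5", "L6"),
    upper_um = c(0, boundaries[-5]),
    lower_um = boundaries
  )
  class(out) <- c("layer_table", class(out))
  out
}

#' Assign recorded neurons to layers by soma depth
#'
#' Half-open interval lookup: a depth exactly at a boundary belongs to the
#' deeper layer.
#'
#' @param depth_um Soma depths from the pia, µm (vectorized).
#' @param table A [layer_table()].
#' @return Character vector of layer names.
#' @export
assign_layer <- function(depth_um, table = layer_table()) {
  if (any(!is.finite(depth_um)) || any(depth_um < 0) ||
      any(depth_um >= max(table$lower_um))) {
    abort(sprintf("Depths must lie in [0, %g) um.", max(table$lower_um)))
  }
  idx <- findInterval(depth_um, c(0, table$lower_um),
                      rightmost.closed = FALSE, left.open = FALSE)
  table$layer[idx]
}

#' Activation criteria for averaged evoked responses
#'
#' The input-mapping thresholds: a cell class is "activated" by an input
#' when the averaged EPSP amplitude exceeds 3 mV and "strongly activated"
#' when it exceeds 7 mV.
#'
#' @param mean_amplitude_mv Averaged EPSP amplitude(s), mV.
#' @param activated_mv,strong_mv The two thresholds, mV.
#' @return Character vector: `"none"`, `"activated"` or `"strong"`.
#' @examples
#' classify_activation(c(2, 5, 8))
#' @export
classify_activation <- function(mean_amplitude_mv,
                                activated_mv = 3, strong_mv = 7) {
  if (any(!is.finite(mean_amplitude_mv))) abort("Amplitudes must be finite.")
  dplyr::case_when(
    mean_amplitude_mv > strong_mv ~ "strong",
    mean_amplitude_mv > activated_mv ~ "activated",
    TRUE ~ "none"
  )
}

#' Assemble a layer-by-cell-type input matrix
#'
#' Groups per-neuron evoked amplitudes for one input source by (layer,
#' cell class) and reports the group mean, the group size and the
#' activation class of the mean. Combinations never recorded are absent
#' from the table (or, with `complete = TRUE`, present with `NA` mean and
#' `n = 0`) — an empty cell is not a zero-amplitude cell.
#'
#' @param records Tibble with columns `layer`, `cell_class`,
#'   `input_source`, `amplitude_mv` (one row per recorded neuron and
#'   source; extra columns are ignored).
#' @param input_source Which input source to tabulate.
#' @param complete Also emit never-recorded combinations with `n = 0`.
#'
#' @return A tibble: `layer`, `cell_class`, `mean_amplitude_mv`, `n`,
#'   `activation_class`.
#' @export
assemble_input_matrix <- function(records, input_source, complete = FALSE) {
  needed <- c("layer", "cell_class", "input_source", "amplitude_mv")
  if (!all(needed %in% names(records))) {
    abort(sprintf("`records` needs columns: %s.", paste(needed, collapse = ", ")))
  }
  sel <- dplyr::filter(records, .data$input_source == !!input_source)
  if (nrow(sel) == 0L) {
    abort(sprintf("No record has a response to input source '%s'.", input_source))
  }
  out <- sel |>
    dplyr::group_by(.data$layer, .data$cell_class) |>
    dplyr::summarise(
      mean_amplitude_mv = mean(.data$amplitude_mv),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(activation_class = classify_activation(.data$mean_amplitude_mv))
  if (complete) {
    grid <- tidyr::expand_grid(
      layer = unique(c(layer_table()$layer, out$layer)),
      cell_class = unique(out$cell_class)
    )
    out <- dplyr::left_join(grid, out, by = c("layer", "cell_class")) |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  }
  dplyr::arrange(out, .data$layer, .data$cell_class)
}

#' Normalize an input matrix to a reference population
#'
#' Divides every group mean by the mean of the reference (layer, cell
#' class) group, which therefore maps to 1 — the convention used when
#' comparing input strengths across cell types (e.g. normalized to the L5
#' pyramidal group defined by the same input).
#'
#' @param matrix An input matrix from [assemble_input_matrix()].
#' @param reference_layer,reference_cell_class The reference group.
#' @return The matrix with an added `normalized_amplitude` column.
#' @export
normalize_strengths <- function(matrix, reference_layer, reference_cell_class) {
  ref <- dplyr::filter(matrix, .data$layer == reference_layer,
                       .data$cell_class == reference_cell_class)
  if (nrow(ref) != 1L || is.na(ref$mean_amplitude_mv)) {
    abort("Reference group is absent from the matrix.")
  }
  if (ref$mean_amplitude_mv <= 0) abort("Reference mean must be > 0.")
  dplyr::mutate(matrix,
                normalized_amplitude = .data$mean_amplitude_mv / ref$mean_amplitude_mv)
}

#' Convergence of two input sources onto single neurons
#'
#' For neurons probed with both input sources (dual-channel optogenetics),
#' bins each neuron into `both` / `only_a` / `only_b` / `neither` by a
#' response criterion on the measured charge (or amplitude) magnitude, and
#' reports counts and percentages. The default criterion follows the
#' detection convention used for evoked currents: a response is real when
#' its magnitude exceeds `threshold`.
#'
#' @param responses Tibble with columns `cell_id`, `source`, `value` (one
#'   row per neuron x source; `value` is the response magnitude — charge
#'   in pC or amplitude in pA).
#' @param source_a,source_b The two input sources to compare.
#' @param threshold Response criterion on `abs(value)`.
#'
#' @return A tibble (`category`, `n`, `pct`) with
#'   `attr(x, "n_total")` set; percentages sum to 100.
#' @examples
#' resp <- tibble::tibble(
#'   cell_id = rep(1:3, each = 2),
#'   source = rep(c("V2M", "ACA"), 3),
#'   value = c(5, 4, 6, 0, 0, 0)
#' )
#' convergence_stats(resp, "V2M", "ACA", threshold = 1)
#' @export
convergence_stats <- function(responses, source_a, source_b, threshold) {
  needed <- c("cell_id", "source", "value")
  if (!all(needed %in% names(responses))) {
    abort(sprintf("`responses` needs columns: %s.", paste(needed, collapse = ", ")))
  }
  wide <- responses |>
    dplyr::filter(.data$source %in% c(source_a, source_b)) |>
    tidyr::pivot_wider(id_cols = "cell_id", names_from = "source",
                       values_from = "value")
  if (!all(c(source_a, source_b) %in% names(wide)) ||
      anyNA(wide[[source_a]]) || anyNA(wide[[source_b]])) {
    abort("Every neuron needs a measured response to both sources.")
  }
  a <- abs(wide[[source_a]]) > threshold
  b <- abs(wide[[source_b]]) > threshold
  category <- factor(
    dplyr::case_when(a & b ~ "both", a ~ "only_a", b ~ "only_b",
                     TRUE ~ "neither"),
    levels = c("both", "only_a", "only_b", "neither")
  )
  counts <- as.integer(table(category))
  out <- tibble(category = levels(category), n = counts) |>
    dplyr::mutate(pct = .data$n / sum(.data$n) * 100)
  attr(out, "n_total") <- nrow(wide)
  out
}
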