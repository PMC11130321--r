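#' Laminar axon-profile operations
#'
#' Background subtraction, peak normalization, per-layer mass fractions
#' and within-layer peak localization for vertical axon-fluorescence
#' profiles. The background estimate comes from a region devoid of
#' labeled axons; subtraction clamps at zero. Normalization divides by
#' the profile maximum so the peak is exactly 1 and is idempotent.
#'
#' @param profile An `axon_profile` (see [generate_axon_profile()]) or any
#'   tibble with `depth_um` and `intensity_au` columns.
#' @param background_au Background fluorescence to subtract, AU (>= 0).
#' @return The modified profile (same class).
#' @examples
#' pr <- generate_axon_profile(c(L1 = 0.13, L6 = 0.87), seed = 1)
#' pr |> subtract_background(5) |> normalize_to_peak() |> layer_fractions()
#' @export
subtract_background <- function(profile, background_au) {
  check_number(background_au, "background_au", min = 0)
  profile$intensity_au <- pmax(profile$intensity_au - background_au, 0)
  profile
}

#' @rdname subtract_background
#' @export
normalize_to_peak <- function(profile) {
  peak <- max(profile$intensity_au)
  if (peak <= 0) abort("All-zero profile: nothing to normalize.")
  profile$intensity_au <- pmax(profile$intensity_au / peak, 0)
  attr(profile, "normalized") <- TRUE
  profile
}

#' @rdname subtract_background
#' @param table A [layer_table()]; defaults to the one attached to the
#'   profile.
#' @return `layer_fractions()`: a tibble (`layer`, `fraction_pct`);
#'   fractions sum to 100.
#' @export
layer_fractions <- function(profile, table = NULL) {
  table <- table %||% attr(profile, "layer_table") %||% layer_table()
  frac <- layer_mass_fractions(profile$depth_um, profile$intensity_au, table)
  tibble(layer = names(frac), fraction_pct = unname(frac))
}

#' @rdname subtract_background
#' @param layer Which layer to localize the peak in.
#' @return `peak_depth_in_layer()`: percent of the layer's depth extent at
#'   which the maximum sits (0 = upper boundary, 100 = lower); ties go to
#'   the shallowest sample.
#' @export
peak_depth_in_layer <- function(profile, layer, table = NULL) {
  table <- table %||% attr(profile, "layer_table") %||% layer_table()
  row <- table[table$layer == layer, ]
  if (nrow(row) != 1L) abort(sprintf("Unknown layer '%s'.", layer))
  sel <- profile$depth_um >= row$upper_um & profile$depth_um <= row$lower_um
  if (!any(sel) || all(profile$intensity_au[sel] <= 0)) {
    abort(sprintf("Layer %s has no positive mass.", layer))
  }
  d <- profile$depth_um[sel]
  peak_at <- d[which.max(profile$intensity_au[sel])]
  (peak_at - row$upper_um) / (row$lower_um - row$upper_um) * 100
}
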