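#' Simulate a laminar axon-fluorescence profile
#'
#' Builds a vertical (pia-to-white-matter) fluorescence profile as a
#' mixture of per-layer blocks — block height proportional to the layer's
#' target weight divided by its width, so weights are target mass
#' fractions — Gaussian-smoothed across depth, plus a constant background
#' and Gaussian noise. The per-layer mass fractions of the smoothed,
#' background-free profile are recorded as ground truth (smoothing leaks a
#' little mass across boundaries, so truth is computed after smoothing).
#'
#' @param layer_targets Named nonnegative weights per layer (names from
#'   `table$layer`); at least one positive.
#' @param table A [layer_table()].
#' @param smoothing_sd_um Gaussian smoothing SD across depth, µm.
#' @param total_mass_au Total integrated signal above background,
#'   AU·µm — sets the signal-to-noise of the profile (the default puts
#'   peak intensities two orders of magnitude above the noise SD, typical
#'   of well-labeled material).
#' @param background_au Constant background fluorescence, AU.
#' @param noise_sd_au Gaussian noise SD, AU.
#' @param grid_um Depth-grid spacing, µm.
#' @param seed Optional integer seed.
#'
#' @return An `axon_profile`: tibble (`depth_um`, `intensity_au`) with the
#'   layer table, the true background and the true per-layer fractions in
#'   its attributes (`trace_meta()` reads them).
#'
#' @examples
#' pr <- generate_axon_profile(c(L1 = 0.13, `L2/3` = 0.1, L4 = 0.12,
#'                               L5 = 0.15, L6 = 0.5), seed = 1)
#' layer_fractions(subtract_background(pr, 5))
#' @export
generate_axon_profile <- function(layer_targets,
                                  table = layer_table(),
                                  smoothing_sd_um = 20,
                                  total_mass_au = 5e4,
                                  background_au = 5,
                                  noise_sd_au = 1,
                                  grid_um = 2,
                                  seed = NULL) {
  if (is.null(names(layer_targets)) ||
      !all(names(layer_targets) %in% table$layer)) {
    abort("`layer_targets` must be named with layers from the layer table.")
  }
  if (any(layer_targets < 0)) abort("Layer weights must be >= 0.")
  if (all(layer_targets == 0)) abort("At least one layer weight must be positive.")
  check_number(background_au, "background_au", min = 0)
  check_number(noise_sd_au, "noise_sd_au", min = 0)

  depth <- seq(0, max(table$lower_um), by = grid_um)
  clean <- numeric(length(depth))
  scale <- total_mass_au / sum(layer_targets)
  for (nm in names(layer_targets)) {
    row <- table[table$layer == nm, ]
    sel <- depth >= row$upper_um & depth < row$lower_um
    clean[sel] <- scale * layer_targets[[nm]] / (row$lower_um - row$upper_um)
  }
  if (smoothing_sd_um > 0) {
    half <- ceiling(3 * smoothing_sd_um / grid_um)
    kern <- stats::dnorm(seq(-half, half) * grid_um, sd = smoothing_sd_um)
    kern <- kern / sum(kern)
    padded <- c(numeric(half), clean, numeric(half))
    clean <- stats::convolve(padded, rev(kern), type = "filter")
  }

  true_frac <- layer_mass_fractions(depth, clean, table)
  intensity <- clean + background_au
  if (noise_sd_au > 0) {
    intensity <- intensity +
      with_local_seed(seed, rnorm(length(depth), 0, noise_sd_au))
  }

  new_axon_profile(
    depth_um = depth, intensity_au = intensity, table = table,
    meta = list(
      target_weights = layer_targets,
      true_fractions_pct = true_frac,
      background_au = background_au,
      smoothing_sd_um = smoothing_sd_um,
      noise_sd_au = noise_sd_au,
      seed = seed
    )
  )
}

new_axon_profile <- function(depth_um, intensity_au, table,
                             meta = list(), normalized = FALSE) {
  if (is.unsorted(depth_um, strictly = TRUE)) {
    abort("`depth_um` must be strictly increasing.")
  }
  out <- tibble(depth_um = depth_um, intensity_au = intensity_au)
  attr(out, "layer_table") <- table
  attr(out, "meta") <- meta
  attr(out, "normalized") <- normalized
  class(out) <- c("axon_profile", class(out))
  out
}

# Per-layer trapezoidal mass fractions (%) of an intensity vector.
layer_mass_fractions <- function(depth, intensity, table) {
  total <- trapz_integral(depth, intensity)
  if (total <= 0) abort("Profile has no mass.")
  frac <- purrr::map_dbl(seq_len(nrow(table)), function(k) {
    sel <- depth >= table$upper_um[k] & depth <= table$lower_um[k]
    trapz_integral(depth[sel], intensity[sel]) / total * 100
  })
  stats::setNames(frac, table$layer)
}
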