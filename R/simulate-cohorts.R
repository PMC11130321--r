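#' Simulate calibrated recording cohorts
#'
#' Cohort-level wrappers around the single-cell simulators, used by the
#' worked examples and the reproduction script. Each cohort is calibrated
#' so that the *generating* group statistics equal a chosen target, and
#' each returns both the traces and a ground-truth table.
#'
#' `simulate_sag_cohort()` draws per-cell target slopes from a normal
#' distribution (truncated at `min_slope` for sag-bearing cells, whose
#' sag amplitude cannot be negative), converts them to sag amplitudes via
#' the closed form, and simulates one voltage-clamp step per cell.
#' With `sag = FALSE` the slope target is implemented as baseline drift
#' instead — the sag-free phenotype whose measured slope scatters around
#' zero.
#'
#' @param n_cells Number of cells.
#' @param mean_slope,sd_slope Across-cell mean and SD of the generated
#'   slope distribution, pA/s. (To match a reported group
#'   `mean ± SEM`, pass `sd_slope = SEM * sqrt(n)`.)
#' @param sag Whether cells carry the sag current (`TRUE`) or express the
#'   target as baseline drift (`FALSE`).
#' @param tau_h_ms Sag activation time constant, ms.
#' @param membrane A [membrane_params()] bundle.
#' @param noise_sd_pa Trace noise SD, pA.
#' @param min_slope Truncation floor for sag-bearing target slopes.
#' @param seed Integer seed.
#'
#' @return A list: `traces` (list of [vc_trace()]), `truth` (tibble with
#'   `cell_id`, `slope_true`).
#' @examples
#' coh <- simulate_sag_cohort(5, mean_slope = 82.5, sd_slope = 35.5, seed = 1)
#' mean(coh$truth$slope_true)
#' @export
simulate_sag_cohort <- function(n_cells, mean_slope, sd_slope,
                                sag = TRUE, tau_h_ms = 300,
                                membrane = membrane_params(),
                                noise_sd_pa = 5, min_slope = 5,
                                seed = 1) {
  check_number(n_cells, "n_cells", min = 1)
  with_local_seed(seed, {
    target <- rnorm(n_cells, mean_slope, sd_slope)
    if (sag) target <- pmax(target, min_slope)
    traces <- purrr::map(seq_len(n_cells), function(k) {
      sg <- if (sag) {
        sag_params(amplitude_pa = sag_amplitude_for_slope(target[k], tau_h_ms),
                   tau_h_ms = tau_h_ms)
      } else {
        sag_params(amplitude_pa = 0, enabled = FALSE,
                   drift_rate_pa_per_s = target[k])
      }
      simulate_voltage_clamp_step(membrane, sg, noise_sd_pa = noise_sd_pa,
                                  seed = sample.int(2^30, 1))
    })
    list(
      traces = traces,
      truth = tibble(cell_id = sprintf("cell%03d", seq_len(n_cells)),
                     slope_true = target)
    )
  })
}

#' @rdname simulate_sag_cohort
#' @param syn A [synapse_params()] bundle shared by all neurons (each
#'   neuron redraws its per-pulse latencies).
#' @param n_trials Trials per neuron.
#' @return `simulate_psc_cohort()`: a list of per-neuron trial lists plus
#'   a `truth` tibble of per-neuron mean programmed latencies.
#' @export
simulate_psc_cohort <- function(n_cells, syn = synapse_params(),
                                n_trials = 5, seed = 1) {
  check_number(n_cells, "n_cells", min = 1)
  with_local_seed(seed, {
    neurons <- purrr::map(seq_len(n_cells), function(k) {
      simulate_psc_train(syn, n_trials = n_trials,
                         seed = sample.int(2^30, 1))
    })
    truth <- tibble(
      cell_id = sprintf("cell%03d", seq_len(n_cells)),
      mean_latency_true_ms = purrr::map_dbl(
        neurons, ~ mean(trace_meta(.x[[1]])$latencies_true_ms))
    )
    list(neurons = neurons, truth = truth)
  })
}

#' @rdname simulate_sag_cohort
#' @param n_burst How many of the `n_cells` carry the burst mechanism.
#' @param rin_sd,threshold_sd Across-cell SDs of input resistance (MΩ)
#'   and spike threshold (mV), modelling cell-to-cell variability.
#' @return `simulate_spiking_cohort()`: a list of [cc_trace()] plus a
#'   `truth` tibble with the generating mode per cell.
#' @export
simulate_spiking_cohort <- function(n_cells, n_burst,
                                    rin_sd = 8, threshold_sd = 1,
                                    seed = 1) {
  check_number(n_cells, "n_cells", min = 1)
  check_number(n_burst, "n_burst", min = 0, max = n_cells)
  with_local_seed(seed, {
    burst <- seq_len(n_cells) <= n_burst
    traces <- purrr::map(seq_len(n_cells), function(k) {
      mem <- membrane_params(
        membrane_resistance = max(rnorm(1, 150, rin_sd), 100),
        membrane_capacitance = 100
      )
      sp <- spiking_params(
        threshold_mv = rnorm(1, -42, threshold_sd),
        burst_enabled = burst[k]
      )
      simulate_current_clamp(mem, sp, seed = sample.int(2^30, 1))
    })
    list(
      traces = traces,
      truth = tibble(cell_id = sprintf("cell%03d", seq_len(n_cells)),
                     mode_true = ifelse(burst, "BS", "RS"))
    )
  })
}

#' Cohort specification
#'
#' A declarative description of a mixed-class recording cohort: how many
#' cells of each class and which parameter presets each class uses. Used
#' by configuration files and the demo driver.
#'
#' @param n_cells_per_class Named integer vector, class -> count.
#' @param class_param_presets Named list, class -> list with any of
#'   `membrane`, `sag`, `synapse`, `spiking` parameter bundles.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cells_per_class, class_param_presets, seed = 1) {
  if (is.null(names(n_cells_per_class)) || any(n_cells_per_class < 0)) {
    abort("`n_cells_per_class` must be a named, nonnegative vector.")
  }
  missing <- setdiff(names(n_cells_per_class), names(class_param_presets))
  if (length(missing)) {
    abort(sprintf("No preset for class(es): %s.", paste(missing, collapse = ", ")))
  }
  structure(
    list(n_cells_per_class = n_cells_per_class,
         class_param_presets = class_param_presets, seed = seed),
    class = "cohort_spec"
  )
}

#' Default class presets for the two L5 pyramidal phenotypes
#'
#' `Pyr_LP`: no sag, regular spiking, slope scattered around zero via
#' drift. `Pyr_ORBvl`: prominent sag calibrated to the high-slope group,
#' burst spiking.
#'
#' @return A named list of presets for [cohort_spec()].
#' @export
default_class_presets <- function() {
  list(
    Pyr_LP = list(
      membrane = membrane_params(),
      sag = sag_params(amplitude_pa = 0, enabled = FALSE),
      spiking = spiking_params(burst_enabled = FALSE),
      synapse = synapse_params(onset_latency_mean_ms = 4.5)
    ),
    Pyr_ORBvl = list(
      membrane = membrane_params(),
      sag = sag_params(amplitude_pa = sag_amplitude_for_slope(82.5), tau_h_ms = 300),
      spiking = spiking_params(burst_enabled = TRUE),
      synapse = synapse_params(onset_latency_mean_ms = 3.7)
    )
  )
}
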