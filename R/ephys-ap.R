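#' Action-potential threshold from the phase plane
#'
#' Computes dV/dt and scans forward from the stimulus onset: the threshold
#' is the voltage at the first sample whose dV/dt exceeds three times the
#' standard deviation of all preceding dV/dt samples (from the scan start
#' up to, but excluding, the candidate), with a minimum of 20 preceding
#' samples before testing begins. At physiological noise the running SD is
#' set by the differentiated noise floor, and the exponential upstroke
#' crosses it within about a millivolt of the true initiation voltage.
#'
#' Because a single differentiated-noise sample can cross three SDs by
#' chance, the crossing must be sustained for `persistence_samples`
#' consecutive samples; the threshold is read at the first sample of that
#' run. A genuine upstroke satisfies this trivially.
#'
#' @param trace A [cc_trace()] containing at least one spike.
#' @param scan_from_ms Scan start, ms. Default: onset of the injected-
#'   current step that precedes the first spike.
#' @param min_presamples Samples required before testing begins.
#' @param persistence_samples Consecutive samples the crossing must hold.
#'
#' @return Threshold voltage, mV (scalar).
#' @examples
#' tr <- simulate_single_ap(seed = 1)
#' detect_ap_threshold(tr)
#' @export
detect_ap_threshold <- function(trace, scan_from_ms = NULL,
                                min_presamples = 20,
                                persistence_samples = 3) {
  t <- trace$time_ms
  v <- trace$voltage_mv
  dt <- t[2] - t[1]
  spikes <- spike_times_from_voltage(trace)
  if (!length(spikes)) abort("No spike in trace.")
  first_spike <- spikes[1]

  if (is.null(scan_from_ms)) {
    # Rising edges only: a spike riding the end of a brief pulse must not
    # anchor the scan to the pulse-off edge.
    pre <- which(t < first_spike & c(0, diff(trace$injected_pa)) > 0)
    scan_from_ms <- if (length(pre)) t[max(pre)] else t[1]
  }
  start <- which(t >= scan_from_ms)[1]
  stop_at <- which(t >= first_spike)[1] # spike peak region upper bound
  dvdt <- c(diff(v) / dt, 0)

  idx <- seq(start, stop_at)
  if (length(idx) <= min_presamples) abort("Fewer than 20 samples precede the spike.")
  x <- dvdt[idx]
  m <- length(x)
  # Running SD of x[1..(i-1)] via cumulative sums.
  cs <- cumsum(x)
  css <- cumsum(x^2)
  k <- seq_len(m)
  var_prev <- (css - cs^2 / k) / pmax(k - 1, 1)
  sd_prev <- sqrt(pmax(c(0, var_prev[-m]), 0)) # sd of preceding samples
  above <- k > min_presamples & x > 3 * sd_prev
  # First run of `persistence_samples` consecutive crossings.
  run <- rle(above)
  stops <- cumsum(run$lengths)
  ok <- which(run$values & run$lengths >= persistence_samples)
  if (!length(ok)) abort("No phase-plane threshold crossing found before the spike peak.")
  first <- stops[ok[1]] - run$lengths[ok[1]] + 1L
  v[idx[first]]
}

#' Depolarizing afterpotential amplitude
#'
#' For a trace segment holding exactly one action potential: finds the
#' fast-AHP minimum after the spike, then the subsequent local voltage
#' maximum; the DAP amplitude is that rebound peak minus the AHP minimum,
#' clamped at 0. Traces that decay monotonically after the AHP score 0 (the
#' convention for absent DAPs).
#'
#' @param trace A [cc_trace()].
#' @param window_ms Two-element window (ms) that must contain exactly one
#'   spike; default the whole trace.
#' @param ahp_search_ms How far after the spike to search for the AHP
#'   minimum, ms.
#' @param dap_search_ms How far after the AHP minimum to search for the
#'   rebound peak, ms.
#'
#' @return DAP amplitude, mV (scalar >= 0).
#' @examples
#' tr <- simulate_single_ap(spiking = spiking_params(burst_enabled = TRUE), seed = 1)
#' measure_dap(tr)
#' @export
measure_dap <- function(trace, window_ms = NULL,
                        ahp_search_ms = 10, dap_search_ms = 60) {
  t <- trace$time_ms
  v <- trace$voltage_mv
  spikes <- spike_times_from_voltage(trace)
  if (!is.null(window_ms)) {
    spikes <- spikes[spikes >= window_ms[1] & spikes <= window_ms[2]]
  }
  if (length(spikes) != 1L) {
    abort(sprintf("Expected exactly one spike in the window, found %d.", length(spikes)))
  }
  peak_idx <- which(t >= spikes[1])[1]
  ahp_sel <- which(t > t[peak_idx] & t <= t[peak_idx] + ahp_search_ms)
  ahp_idx <- ahp_sel[which.min(v[ahp_sel])]
  dap_sel <- which(t > t[ahp_idx] & t <= t[ahp_idx] + dap_search_ms)
  if (!length(dap_sel)) return(0)
  rebound <- max(v[dap_sel])
  arg <- which.max(v[dap_sel])
  # Monotone decay: the "maximum" sits at the segment start, i.e. no rebound.
  if (arg <= 2L) return(0)
  max(rebound - v[ahp_idx], 0)
}

#' Discharge mode at the near-threshold step
#'
#' Finds the first step of the injected sequence that elicits at least one
#' spike (the near-threshold step of the rheobase search) and classifies
#' the response: one spike is regular spiking (RS), a complex of two or
#' more is burst spiking (BS). The instantaneous rate of the first spike
#' pair, `1000/ISI`, is reported when at least two spikes occur.
#'
#' @param trace A [cc_trace()] from a step-sequence protocol (the step
#'   windows are read from the trace metadata, or reconstructed from the
#'   injected current).
#'
#' @return A one-row tibble: `mode` (`"RS"`, `"BS"` or `"undefined"`),
#'   `n_spikes`, `first_pair_rate_hz` (`NA` unless >= 2 spikes),
#'   `step_amplitude_pa` (`NA` when silent).
#' @export
classify_spiking_mode <- function(trace) {
  steps <- trace_meta(trace)$steps %||% steps_from_injected(trace)
  spikes <- spike_times_from_voltage(trace)
  for (k in seq_len(nrow(steps))) {
    in_step <- spikes[spikes >= steps$onset_ms[k] & spikes < steps$offset_ms[k]]
    if (length(in_step) >= 1L) {
      rate <- if (length(in_step) >= 2L) 1000 / (in_step[2] - in_step[1]) else NA_real_
      return(tibble(
        mode = if (length(in_step) >= 2L) "BS" else "RS",
        n_spikes = length(in_step),
        first_pair_rate_hz = rate,
        step_amplitude_pa = steps$amplitude_pa[k]
      ))
    }
  }
  tibble(mode = "undefined", n_spikes = 0L,
         first_pair_rate_hz = NA_real_, step_amplitude_pa = NA_real_)
}

# Spike times as upward 0 mV crossings of the voltage trace.
spike_times_from_voltage <- function(trace, cross_mv = 0) {
  v <- trace$voltage_mv
  up <- which(v[-1] >= cross_mv & v[-length(v)] < cross_mv)
  trace$time_ms[up + 1L]
}

steps_from_injected <- function(trace) {
  inj <- trace$injected_pa
  t <- trace$time_ms
  edges <- which(diff(inj) != 0)
  if (!length(edges)) abort("No current steps found in trace.")
  on <- edges[inj[edges + 1L] != 0] + 1L
  out <- purrr::map(on, function(i) {
    off <- which(t > t[i] & inj != inj[i])
    off <- if (length(off)) off[1] else length(t)
    tibble(amplitude_pa = inj[i], onset_ms = t[i], offset_ms = t[off])
  })
  dplyr::bind_rows(out) |> dplyr::mutate(step = dplyr::row_number(), .before = 1)
}
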