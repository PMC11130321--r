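#' Parameter sets for the recording simulator
#'
#' Constructors for the parameter bundles consumed by the simulator:
#' passive membrane properties, the hyperpolarization-activated (I_h) sag
#' conductance, light-evoked synaptic responses, and spiking dynamics.
#' Each constructor validates its arguments and returns a named list with a
#' class tag, so downstream functions can check what they were given.
#'
#' Units follow slice-electrophysiology convention: resistances in MΩ,
#' capacitance in pF, potentials in mV, currents in pA, times in ms.
#'
#' @param membrane_resistance Input (membrane) resistance in MΩ. Must be > 0.
#' @param membrane_capacitance Whole-cell capacitance in pF. Must be > 0.
#' @param access_resistance Pipette access resistance in MΩ. Must be > 0.
#' @param resting_potential Resting membrane potential in mV.
#' @param holding_potential Voltage-clamp holding potential in mV
#'   (convention: cells held at −70 mV).
#'
#' @return A list with class `"membrane_params"`, `"sag_params"`,
#'   `"synapse_params"` or `"spiking_params"`.
#'
#' @examples
#' membrane_params(membrane_resistance = 150, access_resistance = 15)
#' sag_params(amplitude_pa = 25, tau_h_ms = 300)
#' @export
membrane_params <- function(membrane_resistance = 150,
                            membrane_capacitance = 20,
                            access_resistance = 15,
                            resting_potential = -70,
                            holding_potential = -70) {
  check_number(membrane_resistance, "membrane_resistance", min = 0, strict_min = TRUE)
  check_number(membrane_capacitance, "membrane_capacitance", min = 0, strict_min = TRUE)
  check_number(access_resistance, "access_resistance", min = 0, strict_min = TRUE)
  check_number(resting_potential, "resting_potential")
  check_number(holding_potential, "holding_potential")
  structure(
    list(
      membrane_resistance = membrane_resistance,
      membrane_capacitance = membrane_capacitance,
      access_resistance = access_resistance,
      resting_potential = resting_potential,
      holding_potential = holding_potential
    ),
    class = "membrane_params"
  )
}

#' @rdname membrane_params
#' @param amplitude_pa Steady-state sag-current magnitude (pA) reached at the
#'   step potential; 0 disables the current even when `enabled = TRUE`.
#' @param tau_h_ms Single-exponential activation time constant of the sag
#'   current, in ms. Must be > 0.
#' @param enabled Whether the sag conductance is present at all.
#' @param drift_rate_pa_per_s Linear baseline drift in pA/s added to the
#'   whole trace (models slow electrode drift; contributes one-for-one to
#'   the measured I_h slope).
#' @export
sag_params <- function(amplitude_pa = 0,
                       tau_h_ms = 300,
                       enabled = amplitude_pa > 0,
                       drift_rate_pa_per_s = 0) {
  check_number(amplitude_pa, "amplitude_pa", min = 0)
  check_number(tau_h_ms, "tau_h_ms", min = 0, strict_min = TRUE)
  check_flag(enabled, "enabled")
  check_number(drift_rate_pa_per_s, "drift_rate_pa_per_s")
  structure(
    list(
      amplitude_pa = amplitude_pa,
      tau_h_ms = tau_h_ms,
      enabled = enabled,
      drift_rate_pa_per_s = drift_rate_pa_per_s
    ),
    class = "sag_params"
  )
}

#' @rdname membrane_params
#' @param onset_latency_mean_ms Mean synaptic onset latency after each light
#'   pulse, ms. Monosynaptic optogenetically evoked currents sit around
#'   3–5 ms; disynaptic inhibition around 7–11 ms.
#' @param onset_latency_sd_ms Across-pulse latency jitter SD, ms. One latency
#'   is drawn per pulse per train and shared across trials of the same
#'   neuron (latency is a property of the connection; trial-to-trial jitter
#'   is far smaller than across-connection variability).
#' @param rise_tau_ms,decay_tau_ms Difference-of-exponentials time constants
#'   of the postsynaptic current, ms. `decay_tau_ms > rise_tau_ms > 0`.
#' @param peak_amplitude_pa Peak current in pA; the sign encodes polarity
#'   (negative = inward = EPSC at a −70 mV hold; positive = outward = IPSC
#'   at the excitatory reversal).
#' @param n_pulses Number of light pulses in the train.
#' @param pulse_rate_hz Pulse rate, Hz (the optogenetic trains are 10 Hz).
#' @param noise_sd_pa Gaussian current-noise SD, pA.
#' @export
synapse_params <- function(onset_latency_mean_ms = 4.5,
                           onset_latency_sd_ms = 0.5,
                           rise_tau_ms = 1,
                           decay_tau_ms = 15,
                           peak_amplitude_pa = -200,
                           n_pulses = 10,
                           pulse_rate_hz = 10,
                           noise_sd_pa = 5) {
  check_number(onset_latency_mean_ms, "onset_latency_mean_ms", min = 0)
  check_number(onset_latency_sd_ms, "onset_latency_sd_ms", min = 0)
  check_number(rise_tau_ms, "rise_tau_ms", min = 0, strict_min = TRUE)
  check_number(decay_tau_ms, "decay_tau_ms", min = rise_tau_ms, strict_min = TRUE)
  check_number(peak_amplitude_pa, "peak_amplitude_pa")
  check_number(n_pulses, "n_pulses", min = 1)
  check_number(pulse_rate_hz, "pulse_rate_hz", min = 0, strict_min = TRUE)
  check_number(noise_sd_pa, "noise_sd_pa", min = 0)
  structure(
    list(
      onset_latency_mean_ms = onset_latency_mean_ms,
      onset_latency_sd_ms = onset_latency_sd_ms,
      rise_tau_ms = rise_tau_ms,
      decay_tau_ms = decay_tau_ms,
      peak_amplitude_pa = peak_amplitude_pa,
      n_pulses = as.integer(n_pulses),
      pulse_rate_hz = pulse_rate_hz,
      noise_sd_pa = noise_sd_pa
    ),
    class = "synapse_params"
  )
}

#' @rdname membrane_params
#' @param rheobase_pa Approximate rheobase, pA: informational; the realised
#'   rheobase emerges from `membrane_resistance` and `threshold_mv`.
#' @param threshold_mv Spike-initiation threshold of the exponential
#'   integrate-and-fire dynamics, mV.
#' @param burst_enabled Whether the cell carries the depolarizing
#'   after-current that produces burst spiking and a prominent DAP.
#' @param dap_current_amp_pa Amplitude of the spike-triggered depolarizing
#'   after-current, pA (only applied when `burst_enabled`).
#' @param dap_current_tau_ms Decay time constant of that current, ms. > 0.
#' @param adapt_increment_pa Spike-triggered adaptation (slow AHP) current
#'   increment, pA; this is what limits regular-spiking cells to a single
#'   spike at near-threshold drive.
#' @param adapt_tau_ms Decay time constant of the adaptation current, ms.
#' @param step_sequence Two-column data frame (`amplitude_pa`,
#'   `duration_ms`) of depolarizing current steps, amplitudes strictly
#'   increasing (the rheobase search runs 25 pA per step, 500 ms each).
#' @export
spiking_params <- function(rheobase_pa = 187,
                           threshold_mv = -42,
                           burst_enabled = FALSE,
                           dap_current_amp_pa = if (burst_enabled) 280 else 0,
                           dap_current_tau_ms = 25,
                           adapt_increment_pa = 120,
                           adapt_tau_ms = 600,
                           step_sequence = default_step_sequence()) {
  check_number(rheobase_pa, "rheobase_pa")
  check_number(threshold_mv, "threshold_mv")
  check_flag(burst_enabled, "burst_enabled")
  check_number(dap_current_amp_pa, "dap_current_amp_pa", min = 0)
  check_number(dap_current_tau_ms, "dap_current_tau_ms", min = 0, strict_min = TRUE)
  check_number(adapt_increment_pa, "adapt_increment_pa", min = 0)
  check_number(adapt_tau_ms, "adapt_tau_ms", min = 0, strict_min = TRUE)
  step_sequence <- as_tibble(step_sequence)
  if (!all(c("amplitude_pa", "duration_ms") %in% names(step_sequence)) ||
      nrow(step_sequence) < 1L) {
    abort("`step_sequence` needs columns `amplitude_pa`, `duration_ms` and >= 1 row.")
  }
  if (nrow(step_sequence) > 1L && any(diff(step_sequence$amplitude_pa) <= 0)) {
    abort("`step_sequence` amplitudes must be strictly increasing (rheobase search).")
  }
  structure(
    list(
      rheobase_pa = rheobase_pa,
      threshold_mv = threshold_mv,
      burst_enabled = burst_enabled,
      dap_current_amp_pa = dap_current_amp_pa,
      dap_current_tau_ms = dap_current_tau_ms,
      adapt_increment_pa = adapt_increment_pa,
      adapt_tau_ms = adapt_tau_ms,
      step_sequence = step_sequence
    ),
    class = "spiking_params"
  )
}

#' @rdname membrane_params
#' @param from,to,by Step amplitudes (pA) of the default depolarizing
#'   sequence; durations follow the 500 ms per-step protocol.
#' @param duration_ms Duration of each step, ms.
#' @export
default_step_sequence <- function(from = 100, to = 300, by = 25,
                                  duration_ms = 500) {
  tibble(amplitude_pa = seq(from, to, by = by), duration_ms = duration_ms)
}
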