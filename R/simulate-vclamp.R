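#' Simulate a voltage-clamp step recording
#'
#' Generates the clamp-current response to a hyperpolarizing voltage step
#' (the routine access-resistance test: −10 mV for 300 ms from a −70 mV
#' hold). The response is the sum of a capacitive transient
#' `ΔI_transient = ΔV/Ra` decaying with `τ = Ra·Cm`, a steady ohmic offset
#' `ΔI_steady = ΔV/Rin`, an optional single-exponential sag-current
#' relaxation `A·(1 − exp(−t/τ_h))` measured from step onset, a linear
#' baseline drift, and Gaussian noise. Currents are stored relative to the
#' pre-step holding current.
#'
#' The sag relaxation is stored positive-going so that the slope statistic
#' `ΔI(5→265 ms)/0.260 s` is positive for sag-bearing cells, matching the
#' field's sign convention for I_h slope. The analytic slope implied by the
#' generating parameters is recorded in the trace metadata as `s_true`:
#' `A·(exp(−5/τ_h) − exp(−265/τ_h))/0.260 + drift`, in pA/s.
#'
#' @param membrane A [membrane_params()] bundle.
#' @param sag A [sag_params()] bundle.
#' @param step_dv_mv Voltage-step amplitude, mV (default −10).
#' @param step_duration_ms Step duration, ms; must cover the 265 ms
#'   measurement window.
#' @param pre_ms,post_ms Baseline before and tail after the step, ms
#'   (baseline must be at least 20 ms for the passive-property estimators).
#' @param sampling_khz Sampling rate, kHz.
#' @param noise_sd_pa Gaussian noise SD, pA.
#' @param seed Optional integer seed; the call leaves the caller's RNG
#'   stream untouched.
#'
#' @return A [vc_trace()] whose metadata records the generating parameters
#'   and the analytic slope `s_true`.
#'
#' @examples
#' tr <- simulate_voltage_clamp_step(
#'   membrane_params(access_resistance = 20),
#'   sag_params(amplitude_pa = 25, tau_h_ms = 300),
#'   seed = 1
#' )
#' compute_ih_slope(tr)
#' @export
simulate_voltage_clamp_step <- function(membrane = membrane_params(),
                                        sag = sag_params(),
                                        step_dv_mv = -10,
                                        step_duration_ms = 300,
                                        pre_ms = 50,
                                        post_ms = 50,
                                        sampling_khz = 10,
                                        noise_sd_pa = 0,
                                        seed = NULL) {
  stopifnot(inherits(membrane, "membrane_params"), inherits(sag, "sag_params"))
  check_number(sampling_khz, "sampling_khz", min = 0, strict_min = TRUE)
  if (step_duration_ms < 265) {
    abort("`step_duration_ms` must be >= 265 ms: the slope window runs 5-265 ms.")
  }
  check_number(pre_ms, "pre_ms", min = 20)
  check_number(post_ms, "post_ms", min = 0)
  check_number(noise_sd_pa, "noise_sd_pa", min = 0)

  dt <- 1 / sampling_khz
  n <- round((pre_ms + step_duration_ms + post_ms) * sampling_khz) + 1L
  time_ms <- (seq_len(n) - 1L) * dt

  ra <- membrane$access_resistance
  rin <- membrane$membrane_resistance
  tau_ra <- ra * membrane$membrane_capacitance / 1000 # MΩ·pF = µs -> ms
  di_transient <- step_dv_mv / ra * 1000              # mV/MΩ = nA -> pA
  di_steady <- step_dv_mv / rin * 1000

  # On/off responses are mirrored: the step response evaluated at t and
  # subtracted again at t - duration, so the tail after the step relaxes
  # back to baseline with the same time constants.
  step_response <- function(t) {
    r <- numeric(length(t))
    on <- t >= 0
    tt <- t[on]
    r[on] <- di_steady + (di_transient - di_steady) * exp(-tt / tau_ra)
    if (sag$enabled && sag$amplitude_pa > 0) {
      r[on] <- r[on] + sag$amplitude_pa * (1 - exp(-tt / sag$tau_h_ms))
    }
    r
  }
  rel <- time_ms - pre_ms
  current <- step_response(rel) - step_response(rel - step_duration_ms)
  current <- current + sag$drift_rate_pa_per_s * time_ms / 1000

  if (noise_sd_pa > 0) {
    current <- current +
      with_local_seed(seed, rnorm(n, mean = 0, sd = noise_sd_pa))
  }

  s_sag <- if (sag$enabled && sag$amplitude_pa > 0) {
    sag$amplitude_pa * (exp(-5 / sag$tau_h_ms) - exp(-265 / sag$tau_h_ms)) / 0.260
  } else 0
  s_true <- s_sag + sag$drift_rate_pa_per_s

  vc_trace(
    time_ms = time_ms,
    current_pa = current,
    sampling_khz = sampling_khz,
    step_onset_ms = pre_ms,
    step_dv_mv = step_dv_mv,
    step_duration_ms = step_duration_ms,
    holding_potential_mv = membrane$holding_potential,
    meta = list(
      s_true = s_true,
      ra_true = ra,
      rin_true = rin,
      cm_true = membrane$membrane_capacitance,
      sag_amplitude_pa = if (sag$enabled) sag$amplitude_pa else 0,
      tau_h_ms = sag$tau_h_ms,
      drift_rate_pa_per_s = sag$drift_rate_pa_per_s,
      noise_sd_pa = noise_sd_pa,
      seed = seed
    )
  )
}

#' Analytic I_h slope of a simulated sag relaxation
#'
#' Closed form for the slope statistic of a single-exponential sag current
#' of steady-state magnitude `amplitude_pa` and time constant `tau_h_ms`,
#' evaluated over the 5–265 ms window:
#' `A·(exp(−5/τ_h) − exp(−265/τ_h))/0.260` pA/s. Used both by the simulator
#' (to record ground truth) and to calibrate cohorts to a target group-mean
#' slope.
#'
#' @param amplitude_pa Sag steady-state magnitude, pA.
#' @param tau_h_ms Activation time constant, ms.
#' @return Slope in pA/s.
#' @export
ih_slope_closed_form <- function(amplitude_pa, tau_h_ms) {
  amplitude_pa * (exp(-5 / tau_h_ms) - exp(-265 / tau_h_ms)) / 0.260
}

#' @rdname ih_slope_closed_form
#' @param slope_pa_per_s Target slope, pA/s.
#' @return `sag_amplitude_for_slope()`: the amplitude (pA) whose closed-form
#'   slope equals `slope_pa_per_s`.
#' @export
sag_amplitude_for_slope <- function(slope_pa_per_s, tau_h_ms = 300) {
  slope_pa_per_s * 0.260 / (exp(-5 / tau_h_ms) - exp(-265 / tau_h_ms))
}
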