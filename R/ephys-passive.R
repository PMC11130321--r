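#' Passive properties from a voltage-clamp step
#'
#' Applies Ohm's law to the two components of the step response:
#' `Ra = ΔV/ΔI_transient` from the capacitive transient (the extremum of
#' the baseline-subtracted current within the first 5 ms after step onset)
#' and `Rin = ΔV/ΔI_steady` from the late-step plateau (mean over the last
#' 50 ms of the step). Units: mV/pA = GΩ, reported in MΩ.
#'
#' @param trace A [vc_trace()] with a voltage step and at least 20 ms of
#'   pre-step baseline.
#' @param transient_window_ms Width of the post-onset window searched for
#'   the capacitive peak, ms.
#' @param plateau_window_ms Width of the end-of-step plateau window, ms.
#'
#' @return A one-row tibble: `ra_mohm`, `rin_mohm`, `rmp_mv` (from trace
#'   metadata when present, otherwise `NA`).
#'
#' @examples
#' tr <- simulate_voltage_clamp_step(membrane_params(access_resistance = 20))
#' compute_passive_properties(tr)
#' @export
compute_passive_properties <- function(trace,
                                       transient_window_ms = 5,
                                       plateau_window_ms = 50) {
  p <- trace_protocol(trace)
  if (!is.finite(p$step_onset_ms) || !is.finite(p$step_dv_mv)) {
    abort("Trace has no voltage step recorded in its protocol.")
  }
  if (p$step_onset_ms - trace$time_ms[1] < 20) {
    abort("Need >= 20 ms of pre-step baseline.")
  }
  t <- trace$time_ms
  i <- trace$current_pa
  baseline <- mean(i[t < p$step_onset_ms])

  trans <- i[t >= p$step_onset_ms & t < p$step_onset_ms + transient_window_ms] - baseline
  di_transient <- trans[which.max(abs(trans))]

  pl_start <- p$step_onset_ms + p$step_duration_ms - plateau_window_ms
  pl_end <- p$step_onset_ms + p$step_duration_ms
  di_steady <- mean(i[t >= pl_start & t < pl_end]) - baseline

  if (di_transient == 0 || di_steady == 0) {
    abort("Flat step response: cannot derive resistances.")
  }
  tibble(
    ra_mohm = p$step_dv_mv / di_transient * 1000,
    rin_mohm = p$step_dv_mv / di_steady * 1000,
    rmp_mv = trace_meta(trace)$rmp_mv %||% NA_real_
  )
}

#' Access-resistance recording quality control
#'
#' A recording is excluded if access resistance ever exceeded the limit
#' (40 MΩ) or varied by more than the allowed fraction (20%) over the
#' recording period, the change being judged relative to the first
#' measurement.
#'
#' @param ra_series Access-resistance measurements over the recording, MΩ.
#' @param limit_mohm Absolute ceiling, MΩ.
#' @param max_rel_change Maximum allowed `(max − min)/first`.
#'
#' @return A one-row tibble: `pass` (logical) and `reason`
#'   (`"ok"`, `"ra_limit"` or `"ra_drift"`).
#' @examples
#' qc_recording(c(25, 26, 25))
#' qc_recording(c(20, 26)) # 30% change: fail
#' @export
qc_recording <- function(ra_series, limit_mohm = 40, max_rel_change = 0.20) {
  if (length(ra_series) < 1L || !is.numeric(ra_series)) {
    abort("`ra_series` must contain at least one measurement.")
  }
  if (any(ra_series > limit_mohm)) {
    return(tibble(pass = FALSE, reason = "ra_limit"))
  }
  rel <- (max(ra_series) - min(ra_series)) / ra_series[1]
  if (rel > max_rel_change) {
    return(tibble(pass = FALSE, reason = "ra_drift"))
  }
  tibble(pass = TRUE, reason = "ok")
}

#' I_h slope from a hyperpolarizing voltage-clamp step
#'
#' The sag-current statistic: `I_h slope = ΔI(5→265 ms)/Δt` with
#' `Δt = 260 ms`, where the two endpoint currents are read from the trace
#' at 5 ms and 265 ms after step onset, each locally smoothed with a short
#' boxcar to suppress single-sample noise (unbiased for linear or slowly
#' relaxing signals). Sag — current growing toward the positive-going
#' relaxation during the hyperpolarizing step — yields a positive slope.
#'
#' @param trace A [vc_trace()] whose step covers the 265 ms window.
#' @param smooth_window_ms Boxcar width around each endpoint, ms.
#'
#' @return A one-row tibble: `slope_pa_per_s`, `delta_i_pa`,
#'   `window_start_ms` (5), `window_end_ms` (265). The identity
#'   `slope = delta_i / 0.260` holds exactly.
#'
#' @examples
#' tr <- simulate_voltage_clamp_step(sag = sag_params(amplitude_pa = 25))
#' compute_ih_slope(tr)
#' @export
compute_ih_slope <- function(trace, smooth_window_ms = 2) {
  p <- trace_protocol(trace)
  if (!is.finite(p$step_onset_ms)) {
    abort("Trace has no voltage step recorded in its protocol.")
  }
  if (is.finite(p$step_duration_ms) && p$step_duration_ms < 265) {
    abort("Step shorter than the 265 ms measurement window.")
  }
  t <- trace$time_ms
  if (p$step_onset_ms + 265 + smooth_window_ms / 2 > t[length(t)]) {
    abort("Measurement window exceeds the trace.")
  }
  endpoint <- function(at_ms) {
    sel <- abs(t - (p$step_onset_ms + at_ms)) <= smooth_window_ms / 2
    mean(trace$current_pa[sel])
  }
  delta_i <- endpoint(265) - endpoint(5)
  tibble(
    slope_pa_per_s = delta_i / 0.260,
    delta_i_pa = delta_i,
    window_start_ms = 5,
    window_end_ms = 265
  )
}
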