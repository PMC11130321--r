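#' Evoked postsynaptic current metrics
#'
#' Averages the trials pointwise, subtracts the pre-stimulus baseline, and
#' reports the train's peak amplitude, total charge, and per-pulse onset
#' latencies. Charge is the time integral of the baseline-subtracted
#' averaged current over the integration window, in pC. Onset latency for
#' each pulse is the first time after the pulse at which the averaged
#' current deviates, in the direction of the requested polarity, by more
#' than `3 × baseline SD` and stays beyond that threshold for at least
#' 1 ms continuously. The SD comes from the pre-train baseline; the local
#' reference level is re-measured over the 2 ms before each pulse, so the
#' decaying tail of the previous response in a 10 Hz train cannot
#' masquerade as an onset. Pulses with no qualifying deviation are
#' reported `NA` (including the degenerate zero-noise, zero-signal case,
#' where the baseline SD is 0).
#'
#' @param trials List of [vc_trace()] objects on a common grid (>= 1).
#' @param pulse_times_ms Light-pulse onset times, ms.
#' @param polarity `"EPSC"` (inward, negative) or `"IPSC"` (outward,
#'   positive); orients both the peak search and onset detection.
#' @param baseline_window_ms Length of pre-stimulus baseline, ms (taken
#'   immediately before the first pulse).
#' @param integration_window_ms Charge window: from the first pulse to this
#'   long after the last pulse, ms.
#' @param persistence_ms How long the deviation must persist to count as an
#'   onset, ms.
#'
#' @return A one-row tibble: `polarity`, `peak_amplitude_pa` (signed),
#'   `charge_pc` (signed), `n_trials_averaged`, `mean_latency_ms`, and a
#'   list-column `latencies` holding a tibble (`pulse`, `latency_ms`).
#'
#' @examples
#' trials <- simulate_psc_train(synapse_params(n_pulses = 3), seed = 1)
#' measure_psc(trials, trace_meta(trials[[1]])$pulse_times_ms, "EPSC")
#' @export
measure_psc <- function(trials, pulse_times_ms,
                        polarity = c("EPSC", "IPSC"),
                        baseline_window_ms = 50,
                        integration_window_ms = 400,
                        persistence_ms = 1) {
  polarity <- match.arg(polarity)
  avg <- average_trials(trials, "current_pa")
  t <- avg$time_ms
  i <- avg$value
  dt <- t[2] - t[1]
  first_pulse <- pulse_times_ms[1]

  base_sel <- t >= first_pulse - baseline_window_ms & t < first_pulse
  if (!any(base_sel)) abort("Baseline window lies outside the trace.")
  base_mean <- mean(i[base_sel])
  base_sd <- sd(i[base_sel])
  dev <- i - base_mean

  int_sel <- t >= first_pulse &
    t <= pulse_times_ms[length(pulse_times_ms)] + integration_window_ms
  charge_pc <- trapz_integral(t[int_sel], dev[int_sel]) / 1000
  peak <- if (polarity == "EPSC") min(dev[int_sel]) else max(dev[int_sel])

  npers <- max(1L, round(persistence_ms / dt))
  sign_dir <- if (polarity == "EPSC") -1 else 1
  ends <- c(pulse_times_ms[-1], t[length(t)])
  lat <- purrr::map2_dbl(pulse_times_ms, ends, function(p, e) {
    local_sel <- t >= p - 2 & t < p
    local_base <- if (any(local_sel)) mean(i[local_sel]) else base_mean
    sel <- which(t >= p & t < e)
    above <- sign_dir * (i[sel] - local_base) > 3 * base_sd
    runs <- rle(above)
    stops <- cumsum(runs$lengths)
    ok <- which(runs$values & runs$lengths >= npers)
    if (!length(ok)) return(NA_real_)
    first_idx <- sel[stops[ok[1]] - runs$lengths[ok[1]] + 1L]
    t[first_idx] - p
  })

  tibble(
    polarity = polarity,
    peak_amplitude_pa = peak,
    charge_pc = charge_pc,
    n_trials_averaged = length(trials),
    mean_latency_ms = if (all(is.na(lat))) NA_real_ else mean(lat, na.rm = TRUE),
    latencies = list(tibble(pulse = seq_along(pulse_times_ms), latency_ms = lat))
  )
}

#' Evoked postsynaptic potential amplitude
#'
#' Trials are averaged pointwise first; the amplitude is the maximum of
#' the averaged voltage minus the pre-stimulus baseline mean, within the
#' response window after the first pulse (the per-train statistic used for
#' the activation criteria is, by default, the first-pulse response).
#'
#' @param trials List of [cc_trace()] objects on a common grid.
#' @param stim_times_ms Stimulus onset times, ms.
#' @param baseline_window_ms Pre-stimulus baseline length, ms; must end at
#'   or before the first stimulus.
#' @param response_window_ms Response window length after the first
#'   stimulus, ms.
#'
#' @return A one-row tibble: `amplitude_mv`, `n_trials_averaged`,
#'   `activation_class` (from [classify_activation()]).
#' @export
measure_psp <- function(trials, stim_times_ms,
                        baseline_window_ms = 50,
                        response_window_ms = 80) {
  avg <- average_trials(trials, "voltage_mv")
  t <- avg$time_ms
  v <- avg$value
  first_stim <- stim_times_ms[1]
  if (baseline_window_ms <= 0 || response_window_ms <= 0) {
    abort("Windows must be positive.")
  }
  if (first_stim - baseline_window_ms < t[1]) {
    abort("Baseline window extends before the trace (overlaps no clean baseline).")
  }
  base_sel <- t >= first_stim - baseline_window_ms & t < first_stim
  resp_sel <- t >= first_stim & t <= first_stim + response_window_ms
  if (!any(resp_sel)) abort("Response window lies outside the trace.")
  amplitude <- max(v[resp_sel] - mean(v[base_sel]))
  tibble(
    amplitude_mv = amplitude,
    n_trials_averaged = length(trials),
    activation_class = classify_activation(amplitude)
  )
}

#' Inhibition fraction of total evoked synaptic charge
#'
#' `IPSC_charge / (IPSC_charge + EPSC_charge)`, computed on charge
#' magnitudes; bounded in \[0, 1\].
#'
#' @param ipsc_charge_pc,epsc_charge_pc Charge magnitudes, pC (signs are
#'   dropped). Vectors recycle in the usual way.
#' @return Numeric fraction(s) in \[0, 1\].
#' @examples
#' inhibition_fraction(1, 3) # 0.25
#' @export
inhibition_fraction <- function(ipsc_charge_pc, epsc_charge_pc) {
  i <- abs(ipsc_charge_pc)
  e <- abs(epsc_charge_pc)
  if (any(i + e == 0)) {
    abort("Both charges are zero: inhibition fraction undefined.")
  }
  i / (i + e)
}

# Pointwise trial average; validates a shared time grid.
average_trials <- function(trials, column) {
  if (!is.list(trials) || length(trials) < 1L) {
    abort("`trials` must be a nonempty list of traces.")
  }
  t0 <- trials[[1]]$time_ms
  vals <- purrr::map(trials, function(tr) {
    if (nrow(tr) != length(t0) || any(abs(tr$time_ms - t0) > 1e-9)) {
      abort("All trials must share one time grid.")
    }
    tr[[column]]
  })
  tibble(time_ms = t0, value = Reduce(`+`, vals) / length(vals))
}
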