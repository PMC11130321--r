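#' Simulate optogenetically evoked postsynaptic current trains
#'
#' Emulates voltage-clamp recordings of light-train-evoked postsynaptic
#' currents (the 10 Hz optogenetic protocol). Each pulse is followed, after
#' a jittered onset latency, by a difference-of-exponentials current
#' `A·(exp(−t/τ_decay) − exp(−t/τ_rise))` normalized to peak `A`; pulses
#' sum linearly. One latency is drawn per pulse per train and shared across
#' trials of the neuron, so trial averaging does not smear the onset — the
#' across-pulse scatter models connection-to-connection latency
#' variability.
#'
#' @param syn A [synapse_params()] bundle.
#' @param pulse_times_ms Light-pulse onset times, ms, sorted and
#'   nonnegative. Default: `n_pulses` at `pulse_rate_hz` starting at
#'   `pre_ms`.
#' @param sampling_khz Sampling rate, kHz.
#' @param n_trials Number of trials to simulate (recordings average 5).
#' @param pre_ms Baseline before the first pulse, ms (onset detection uses
#'   a 50 ms pre-stimulus baseline, so keep at least that).
#' @param post_ms Tail after the last pulse, ms.
#' @param seed Optional integer seed.
#'
#' @return A list of [vc_trace()] objects (one per trial). Each carries
#'   metadata: `pulse_times_ms`, per-pulse `latencies_true_ms` and absolute
#'   `onset_times_true_ms`, and the generating parameters.
#'
#' @examples
#' trials <- simulate_psc_train(synapse_params(n_pulses = 3), seed = 1)
#' measure_psc(trials, trace_meta(trials[[1]])$pulse_times_ms, "EPSC")
#' @export
simulate_psc_train <- function(syn = synapse_params(),
                               pulse_times_ms = NULL,
                               sampling_khz = 10,
                               n_trials = 5,
                               pre_ms = 100,
                               post_ms = 400,
                               seed = NULL) {
  stopifnot(inherits(syn, "synapse_params"))
  check_number(sampling_khz, "sampling_khz", min = 0, strict_min = TRUE)
  check_number(n_trials, "n_trials", min = 1)
  check_number(pre_ms, "pre_ms", min = 0)
  check_number(post_ms, "post_ms", min = 0)

  if (is.null(pulse_times_ms)) {
    pulse_times_ms <- pre_ms + (seq_len(syn$n_pulses) - 1L) * 1000 / syn$pulse_rate_hz
  }
  if (is.unsorted(pulse_times_ms, strictly = FALSE) || any(pulse_times_ms < 0)) {
    abort("`pulse_times_ms` must be sorted and nonnegative.")
  }
  if (length(pulse_times_ms) > 1L &&
      any(diff(pulse_times_ms) < syn$rise_tau_ms)) {
    warn("Pulses closer than `rise_tau_ms`: responses will summate.")
  }

  dt <- 1 / sampling_khz
  total_ms <- max(pulse_times_ms) + post_ms
  n <- round(total_ms * sampling_khz) + 1L
  time_ms <- (seq_len(n) - 1L) * dt

  with_local_seed(seed, {
    lat <- syn$onset_latency_mean_ms +
      rnorm(length(pulse_times_ms), 0, syn$onset_latency_sd_ms)
    lat <- pmax(lat, 0)
    onsets <- pulse_times_ms + lat

    # Peak-normalized difference of exponentials.
    tpk <- log(syn$decay_tau_ms / syn$rise_tau_ms) *
      syn$rise_tau_ms * syn$decay_tau_ms / (syn$decay_tau_ms - syn$rise_tau_ms)
    gmax <- exp(-tpk / syn$decay_tau_ms) - exp(-tpk / syn$rise_tau_ms)

    clean <- numeric(n)
    if (syn$peak_amplitude_pa != 0) {
      for (o in onsets) {
        tt <- time_ms - o
        on <- tt >= 0
        clean[on] <- clean[on] + syn$peak_amplitude_pa / gmax *
          (exp(-tt[on] / syn$decay_tau_ms) - exp(-tt[on] / syn$rise_tau_ms))
      }
    }

    meta <- list(
      pulse_times_ms = pulse_times_ms,
      latencies_true_ms = lat,
      onset_times_true_ms = onsets,
      peak_amplitude_pa = syn$peak_amplitude_pa,
      rise_tau_ms = syn$rise_tau_ms,
      decay_tau_ms = syn$decay_tau_ms,
      noise_sd_pa = syn$noise_sd_pa,
      seed = seed
    )
    purrr::map(seq_len(n_trials), function(trial) {
      cur <- clean
      if (syn$noise_sd_pa > 0) cur <- cur + rnorm(n, 0, syn$noise_sd_pa)
      tr <- vc_trace(time_ms, cur, sampling_khz,
                     holding_potential_mv = -70,
                     meta = c(meta, list(trial = trial)))
      attr(tr, "protocol")$kind <- "psc_train"
      tr
    })
  })
}

#' Analytic charge of one simulated postsynaptic current
#'
#' Closed-form time integral of the peak-normalized difference of
#' exponentials, `A·(τ_decay − τ_rise)/gmax`, in pC. Used as the
#' conservation oracle for train charge.
#'
#' @param syn A [synapse_params()] bundle.
#' @return Single-pulse charge in pC (signed like the peak amplitude).
#' @export
psc_unit_charge <- function(syn) {
  stopifnot(inherits(syn, "synapse_params"))
  tpk <- log(syn$decay_tau_ms / syn$rise_tau_ms) *
    syn$rise_tau_ms * syn$decay_tau_ms / (syn$decay_tau_ms - syn$rise_tau_ms)
  gmax <- exp(-tpk / syn$decay_tau_ms) - exp(-tpk / syn$rise_tau_ms)
  syn$peak_amplitude_pa / gmax * (syn$decay_tau_ms - syn$rise_tau_ms) / 1000
}
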