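#' Simulate a current-clamp step-sequence recording
#'
#' Integrates an exponential integrate-and-fire neuron through a sequence
#' of depolarizing current steps (the 25 pA / 500 ms rheobase-search
#' protocol). Subthreshold steps produce passive charging; steps at or
#' above rheobase produce spikes. Two spike-triggered currents shape the
#' discharge mode: a slow adaptation (AHP) current that limits
#' regular-spiking cells to a single action potential at near-threshold
#' drive, and — when `burst_enabled` — a depolarizing after-current that
#' both re-ignites the cell within a few milliseconds (burst spiking) and
#' produces the depolarizing afterpotential (DAP) seen after single spikes.
#'
#' Spikes are pasted as a stereotyped waveform (0.3 ms rise to +35 mV,
#' 0.6 ms fall to the fast-AHP minimum) and integration resumes from the
#' AHP voltage. Ground-truth spike times, per-step windows and the
#' generating mode are stored in the trace metadata.
#'
#' @param membrane A [membrane_params()] bundle (`membrane_resistance` and
#'   `membrane_capacitance` set the membrane time constant
#'   `τ_m = Rm·Cm`).
#' @param spiking A [spiking_params()] bundle.
#' @param sampling_khz Sampling rate, kHz.
#' @param pre_ms Initial rest before the first step, ms.
#' @param gap_ms Rest between steps, ms.
#' @param noise_sd_mv Gaussian voltage-noise SD, mV, added to the output.
#' @param seed Optional integer seed.
#'
#' @return A [cc_trace()]. Metadata: `spike_times_ms`, `steps` (tibble with
#'   per-step onset/offset/amplitude), `mode_true` (`"RS"`/`"BS"`), and
#'   `silent` flag when no step elicited a spike.
#'
#' @examples
#' tr <- simulate_current_clamp(spiking = spiking_params(), seed = 1)
#' classify_spiking_mode(tr)
#' @export
simulate_current_clamp <- function(membrane = membrane_params(membrane_capacitance = 100),
                                   spiking = spiking_params(),
                                   sampling_khz = 10,
                                   pre_ms = 100,
                                   gap_ms = 250,
                                   noise_sd_mv = 0.1,
                                   seed = NULL) {
  stopifnot(inherits(membrane, "membrane_params"), inherits(spiking, "spiking_params"))
  check_number(sampling_khz, "sampling_khz", min = 0, strict_min = TRUE)
  check_number(noise_sd_mv, "noise_sd_mv", min = 0)
  steps <- spiking$step_sequence
  if (nrow(steps) < 1L) abort("`step_sequence` must be nonempty.")

  dt <- 1 / sampling_khz
  onsets <- pre_ms + c(0, cumsum(head(steps$duration_ms, -1) + gap_ms))
  offsets <- onsets + steps$duration_ms
  total_ms <- offsets[length(offsets)] + gap_ms
  n <- round(total_ms * sampling_khz) + 1L
  time_ms <- (seq_len(n) - 1L) * dt

  injected <- numeric(n)
  for (k in seq_len(nrow(steps))) {
    injected[time_ms >= onsets[k] & time_ms < offsets[k]] <- steps$amplitude_pa[k]
  }

  sim <- integrate_eif(
    injected = injected, dt = dt,
    e_l = membrane$resting_potential,
    rm = membrane$membrane_resistance,
    tau_m = membrane$membrane_resistance * membrane$membrane_capacitance / 1000,
    v_th = spiking$threshold_mv,
    dap_amp = if (spiking$burst_enabled) spiking$dap_current_amp_pa else 0,
    dap_tau = spiking$dap_current_tau_ms,
    adapt_b = spiking$adapt_increment_pa,
    adapt_tau = spiking$adapt_tau_ms
  )

  v <- sim$v
  if (noise_sd_mv > 0) {
    v <- v + with_local_seed(seed, rnorm(n, 0, noise_sd_mv))
  }
  spike_times <- time_ms[sim$spike_idx]

  cc_trace(
    time_ms = time_ms, voltage_mv = v, injected_pa = injected,
    sampling_khz = sampling_khz,
    meta = list(
      spike_times_ms = spike_times,
      steps = tibble(step = seq_len(nrow(steps)),
                     amplitude_pa = steps$amplitude_pa,
                     onset_ms = onsets, offset_ms = offsets),
      mode_true = if (spiking$burst_enabled) "BS" else "RS",
      threshold_true_mv = spiking$threshold_mv,
      silent = length(spike_times) == 0L,
      noise_sd_mv = noise_sd_mv,
      seed = seed
    )
  )
}

#' @rdname simulate_current_clamp
#' @param amplitude_pa,duration_ms Geometry of the brief depolarizing pulse
#'   used to elicit a single action potential for threshold and DAP
#'   analysis. The moderate default amplitude keeps the initial passive
#'   dV/dt below the phase-plane detector's noise floor; the pulse is
#'   terminated 1 ms after the spike (as the experimenter's brief pulse
#'   is), so burst-capable cells show their DAP without firing a doublet.
#' @param post_ms Tail after the pulse, ms (long enough to cover the
#'   fast AHP and any DAP).
#' @export
simulate_single_ap <- function(membrane = membrane_params(membrane_capacitance = 100),
                               spiking = spiking_params(),
                               amplitude_pa = 260,
                               duration_ms = 30,
                               sampling_khz = 10,
                               pre_ms = 100,
                               post_ms = 150,
                               noise_sd_mv = 0.1,
                               seed = NULL) {
  sp <- spiking
  sp$step_sequence <- tibble(amplitude_pa = amplitude_pa,
                             duration_ms = duration_ms)
  tr <- simulate_current_clamp(membrane, sp, sampling_khz = sampling_khz,
                               pre_ms = pre_ms, gap_ms = post_ms,
                               noise_sd_mv = noise_sd_mv, seed = seed)
  spikes <- trace_meta(tr)$spike_times_ms
  if (length(spikes)) {
    cut_ms <- spikes[1] + 1
    if (cut_ms < pre_ms + duration_ms) {
      sp$step_sequence <- tibble(amplitude_pa = amplitude_pa,
                                 duration_ms = cut_ms - pre_ms)
      tr <- simulate_current_clamp(membrane, sp, sampling_khz = sampling_khz,
                                   pre_ms = pre_ms,
                                   gap_ms = post_ms + (pre_ms + duration_ms - cut_ms),
                                   noise_sd_mv = noise_sd_mv, seed = seed)
    }
  }
  tr
}

# Euler integration of the exponential integrate-and-fire dynamics with a
# pasted spike waveform. delta_t = 0.4 mV keeps spike initiation sharp so
# the phase-plane threshold sits within ~1 mV of v_th.
integrate_eif <- function(injected, dt, e_l, rm, tau_m, v_th,
                          dap_amp, dap_tau, adapt_b, adapt_tau,
                          delta_t = 0.3, v_cut = v_th + 10,
                          v_peak = 35, ahp_drop = 16,
                          rise_ms = 0.3, fall_ms = 0.6) {
  n <- length(injected)
  v <- numeric(n)
  v[1] <- e_l
  v_ahp <- v_th - ahp_drop
  n_up <- max(1L, round(rise_ms / dt))
  n_down <- max(1L, round(fall_ms / dt))
  dec_dap <- exp(-dt / dap_tau)
  dec_w <- exp(-dt / adapt_tau)
  i_dap <- 0
  w <- 0
  spike_idx <- integer(0)

  i <- 1L
  while (i < n) {
    drive <- -(v[i] - e_l) + delta_t * exp(min((v[i] - v_th) / delta_t, 20)) +
      rm * (injected[i] + i_dap - w) / 1000
    vn <- v[i] + dt / tau_m * drive
    i_dap <- i_dap * dec_dap
    w <- w * dec_w
    if (vn >= v_cut) {
      spike_idx <- c(spike_idx, i)
      up <- i + seq_len(n_up)
      down <- i + n_up + seq_len(n_down)
      up <- up[up <= n]; down <- down[down <= n]
      if (length(up)) {
        v[up] <- v[i] + (v_peak - v[i]) *
          (1 - cos(pi * seq_along(up) / n_up)) / 2
      }
      if (length(down)) {
        v[down] <- v_peak + (v_ahp - v_peak) *
          (1 - cos(pi * seq_along(down) / n_down)) / 2
      }
      j <- min(i + n_up + n_down, n)
      v[j] <- v_ahp
      i_dap <- i_dap * dec_dap^(j - i) + dap_amp
      w <- w * dec_w^(j - i) + adapt_b
      i <- j
    } else {
      v[i + 1L] <- vn
      i <- i + 1L
    }
  }
  list(v = v, spike_idx = spike_idx)
}
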