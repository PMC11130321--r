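test_that("zero-amplitude trains are noise-only", {
  syn <- synapse_params(peak_amplitude_pa = 0, noise_sd_pa = 0, n_pulses = 3)
  trials <- simulate_psc_train(syn, seed = 1)
  expect_true(all(trials[[1]]$current_pa == 0))
})

test_that("zero jitter and zero noise give exact programmed onsets", {
  syn <- synapse_params(onset_latency_mean_ms = 4.5, onset_latency_sd_ms = 0,
                        noise_sd_pa = 0, n_pulses = 5)
  trials <- simulate_psc_train(syn, seed = 1)
  meta <- trace_meta(trials[[1]])
  expect_equal(meta$latencies_true_ms, rep(4.5, 5))
  m <- measure_psc(trials, meta$pulse_times_ms, "EPSC")
  lat <- m$latencies[[1]]$latency_ms
  # Zero-noise baseline SD is 0, so the first nonzero deviation is the
  # onset; grid resolution is 0.1 ms.
  expect_true(all(abs(lat - 4.5) <= 0.1 + 1e-9))
})

test_that("train charge is conserved relative to the analytic single-pulse charge", {
  syn <- synapse_params(n_pulses = 10, pulse_rate_hz = 10, decay_tau_ms = 20,
                        onset_latency_sd_ms = 0, noise_sd_pa = 0)
  trials <- simulate_psc_train(syn, sampling_khz = 20, post_ms = 600, seed = 1)
  m <- measure_psc(trials, trace_meta(trials[[1]])$pulse_times_ms, "EPSC",
                   integration_window_ms = 600)
  expect_equal(m$charge_pc, 10 * psc_unit_charge(syn), tolerance = 0.05)
})

test_that("per-pulse latencies are shared across trials of one neuron", {
  syn <- synapse_params(onset_latency_sd_ms = 0.5, n_pulses = 4)
  trials <- simulate_psc_train(syn, n_trials = 3, seed = 5)
  lat <- purrr::map(trials, ~ trace_meta(.x)$latencies_true_ms)
  expect_identical(lat[[1]], lat[[2]])
  expect_identical(lat[[1]], lat[[3]])
})

test_that("generation is deterministic under a seed", {
  a <- simulate_psc_train(synapse_params(), seed = 3)
  b <- simulate_psc_train(synapse_params(), seed = 3)
  expect_identical(purrr::map(a, "current_pa"), purrr::map(b, "current_pa"))
})

test_that("overlapping pulses warn but still simulate", {
  syn <- synapse_params(rise_tau_ms = 5, decay_tau_ms = 30, n_pulses = 2)
  expect_warning(simulate_psc_train(syn, pulse_times_ms = c(100, 102), seed = 1),
                 "summate")
})

test_that("unsorted pulse times are rejected", {
  expect_error(simulate_psc_train(synapse_params(), pulse_times_ms = c(100, 50)),
               "sorted")
})
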