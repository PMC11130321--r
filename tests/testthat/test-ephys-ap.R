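test_that("phase-plane threshold sits within 2 mV of the programmed initiation voltage", {
  for (seed in c(1, 7, 13)) {
    tr <- simulate_single_ap(seed = seed)
    thr <- detect_ap_threshold(tr)
    expect_lt(abs(thr - trace_meta(tr)$threshold_true_mv), 2)
  }
})

test_that("threshold detection is deterministic and errors without a spike", {
  tr <- simulate_single_ap(seed = 2)
  expect_identical(detect_ap_threshold(tr), detect_ap_threshold(tr))
  flat <- simulate_single_ap(amplitude_pa = 50, seed = 2) # subthreshold
  expect_error(detect_ap_threshold(flat), "No spike")
})

test_that("DAP amplitude is the rebound above the fast-AHP minimum", {
  # Hand-built: spike at 100 ms, AHP to -55 mV, rebound peak -50 mV.
  skhz <- 10
  t <- seq(0, 300, by = 1 / skhz)
  v <- rep(-70, length(t))
  v[t >= 100 & t < 101] <- 30
  v[t >= 101 & t < 103] <- -55
  bump <- t >= 103 & t < 123
  v[bump] <- -55 + 5 * sin(pi * (t[bump] - 103) / 20)
  v[t >= 123] <- -70
  tr <- cc_trace(t, v, rep(0, length(t)), skhz)
  expect_equal(measure_dap(tr), 5, tolerance = 0.01)
})

test_that("monotonic post-AHP decay scores a DAP of zero", {
  tr <- simulate_single_ap(spiking = spiking_params(burst_enabled = FALSE),
                           seed = 3)
  expect_identical(measure_dap(tr), 0)
})

test_that("burst-preset cells have larger DAPs than regular-spiking cells", {
  dap_bs <- measure_dap(simulate_single_ap(
    spiking = spiking_params(burst_enabled = TRUE), seed = 4))
  dap_rs <- measure_dap(simulate_single_ap(
    spiking = spiking_params(burst_enabled = FALSE), seed = 4))
  expect_gt(dap_bs, dap_rs + 1)
})

test_that("DAP measurement rejects windows without exactly one spike", {
  expect_error(measure_dap(toy_spike_trace(c(100, 120))), "exactly one")
  expect_error(measure_dap(toy_spike_trace(numeric(0))), "exactly one")
})

test_that("spiking mode follows the near-threshold spike count", {
  t <- seq(0, 700, by = 0.1)
  inj <- ifelse(t >= 50 & t < 650, 200, 0)
  single <- toy_spike_trace(100, total_ms = 700)
  single$injected_pa <- inj
  cls <- classify_spiking_mode(single)
  expect_identical(cls$mode, "RS")

  burst <- toy_spike_trace(c(100, 105, 180), total_ms = 700)
  burst$injected_pa <- inj
  cls2 <- classify_spiking_mode(burst)
  expect_identical(cls2$mode, "BS")
  expect_equal(cls2$first_pair_rate_hz, 200) # 1000 / 5 ms
  expect_identical(cls2$n_spikes, 3L)
})
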