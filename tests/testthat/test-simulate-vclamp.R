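test_that("sag-free, drift-free traces have zero measured slope", {
  tr <- simulate_voltage_clamp_step(membrane_params(),
                                    sag_params(amplitude_pa = 0, enabled = FALSE))
  # The capacitive transient leaves a sub-0.001 pA residue at the 5 ms
  # endpoint; the slope is zero to well under 0.01 pA/s.
  expect_equal(compute_ih_slope(tr)$slope_pa_per_s, 0, tolerance = 0.01)
  expect_equal(trace_meta(tr)$s_true, 0)
})

test_that("closed-form sag slope matches the estimator on noise-free traces", {
  # A = 25 pA, tau_h = 300 ms: S = 25 (e^(-5/300) - e^(-265/300)) / 0.260.
  s_expected <- 25 * (exp(-5 / 300) - exp(-265 / 300)) / 0.260
  expect_equal(s_expected, 54.81431, tolerance = 1e-6)
  tr <- simulate_voltage_clamp_step(membrane_params(),
                                    sag_params(amplitude_pa = 25, tau_h_ms = 300))
  expect_equal(trace_meta(tr)$s_true, s_expected, tolerance = 1e-12)
  est <- compute_ih_slope(tr)$slope_pa_per_s
  expect_lt(abs(est - s_expected) / s_expected, 0.01)

  # The tighter oracle bound, across parameter settings.
  for (pars in list(c(10, 150), c(40, 300), c(60, 500))) {
    tr <- simulate_voltage_clamp_step(
      membrane_params(), sag_params(amplitude_pa = pars[1], tau_h_ms = pars[2]))
    expect_lt(abs(compute_ih_slope(tr)$slope_pa_per_s - trace_meta(tr)$s_true) /
                trace_meta(tr)$s_true, 1e-3)
  }
})

test_that("capacitive transient follows Ohm's law", {
  tr <- simulate_voltage_clamp_step(membrane_params(access_resistance = 20),
                                    sag_params())
  p <- trace_protocol(tr)
  onset_idx <- which(tr$time_ms >= p$step_onset_ms)[1]
  expect_equal(tr$current_pa[onset_idx], -500, tolerance = 1e-8)
})

test_that("drift contributes one-for-one to the slope", {
  tr <- simulate_voltage_clamp_step(
    membrane_params(),
    sag_params(amplitude_pa = 0, enabled = FALSE, drift_rate_pa_per_s = -3.1))
  expect_equal(compute_ih_slope(tr)$slope_pa_per_s, -3.1, tolerance = 1e-3)
})

test_that("measured slope is strictly increasing in sag amplitude", {
  amps <- c(5, 15, 30, 60, 120)
  slopes <- vapply(amps, function(a) {
    tr <- simulate_voltage_clamp_step(membrane_params(),
                                      sag_params(amplitude_pa = a))
    compute_ih_slope(tr)$slope_pa_per_s
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
})

test_that("simulation is deterministic under a seed and leaves the RNG alone", {
  a <- simulate_voltage_clamp_step(noise_sd_pa = 3, seed = 11)
  b <- simulate_voltage_clamp_step(noise_sd_pa = 3, seed = 11)
  expect_identical(a$current_pa, b$current_pa)
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_voltage_clamp_step(noise_sd_pa = 3, seed = 12))
  expect_identical(.Random.seed, before)
})

test_that("invalid protocols are rejected", {
  expect_error(simulate_voltage_clamp_step(step_duration_ms = 200), "265")
  expect_error(simulate_voltage_clamp_step(sampling_khz = 0), "sampling_khz")
  expect_error(simulate_voltage_clamp_step(pre_ms = 5), "pre_ms")
})
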