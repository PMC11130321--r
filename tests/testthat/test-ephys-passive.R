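test_that("resistances follow Ohm's law on clean steps", {
  tr <- simulate_voltage_clamp_step(
    membrane_params(access_resistance = 20, membrane_resistance = 100),
    sag_params())
  pp <- compute_passive_properties(tr)
  expect_equal(pp$ra_mohm, 20, tolerance = 1e-6)   # -10 mV / -500 pA
  expect_equal(pp$rin_mohm, 100, tolerance = 1e-3) # -10 mV / -100 pA
})

test_that("passive properties are recovered within 10% under noise", {
  tr <- simulate_voltage_clamp_step(
    membrane_params(access_resistance = 15, membrane_resistance = 150),
    sag_params(), noise_sd_pa = 2, seed = 8)
  pp <- compute_passive_properties(tr)
  expect_lt(abs(pp$ra_mohm - 15) / 15, 0.10)
  expect_lt(abs(pp$rin_mohm - 150) / 150, 0.10)
})

test_that("recording QC applies the resistance limit and drift rule", {
  expect_true(qc_recording(c(25, 26, 25))$pass)
  r1 <- qc_recording(45)
  expect_false(r1$pass)
  expect_identical(r1$reason, "ra_limit")
  r2 <- qc_recording(c(20, 26)) # 30% change relative to the first value
  expect_false(r2$pass)
  expect_identical(r2$reason, "ra_drift")
  expect_true(qc_recording(c(20, 23))$pass) # 15% change
  expect_error(qc_recording(numeric(0)), "at least one")
})

test_that("the slope statistic is the forced linear-ramp value", {
  # A linear current ramp from -10 pA at 5 ms to +16 pA at 265 ms post
  # onset: delta_i = 26 pA, slope = 100 pA/s.
  skhz <- 10
  t <- seq(0, 400, by = 1 / skhz)
  onset <- 50
  i <- ifelse(t >= onset, -10 + 26 * (t - onset - 5) / 260, 0)
  tr <- vc_trace(t, i, skhz, step_onset_ms = onset, step_dv_mv = -10,
                 step_duration_ms = 300)
  m <- compute_ih_slope(tr)
  expect_equal(m$slope_pa_per_s, 100, tolerance = 1e-9)
  expect_equal(m$delta_i_pa, 26, tolerance = 1e-9)
})

test_that("slope times 0.260 s equals delta_i exactly, always", {
  for (seed in 1:5) {
    tr <- simulate_voltage_clamp_step(
      membrane_params(), sag_params(amplitude_pa = 10 * seed),
      noise_sd_pa = 4, seed = seed)
    m <- compute_ih_slope(tr)
    expect_identical(m$slope_pa_per_s * 0.260, m$delta_i_pa)
  }
})

test_that("windows that leave the trace are rejected", {
  t <- seq(0, 100, by = 0.1)
  tr <- vc_trace(t, numeric(length(t)), 10, step_onset_ms = 50,
                 step_dv_mv = -10, step_duration_ms = NA_real_)
  expect_error(compute_ih_slope(tr), "exceeds")
  expect_error(compute_passive_properties(vc_trace(t, numeric(length(t)), 10)),
               "no voltage step")
})
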