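test_that("flat traces yield zero charge and no onsets", {
  tr <- rect_pulse_trace(0, 200, 210)
  m <- measure_psc(list(tr), pulse_times_ms = 100, polarity = "EPSC")
  expect_equal(m$charge_pc, 0)
  expect_true(is.na(m$latencies[[1]]$latency_ms))
})

test_that("a rectangular 100 pA x 10 ms pulse carries 1 pC", {
  tr <- rect_pulse_trace(100, 200, 210)
  m <- measure_psc(list(tr), pulse_times_ms = 150, polarity = "IPSC")
  expect_equal(m$charge_pc, 1, tolerance = 0.01)
})

test_that("onset latency recovery stays within 0.3 ms across a cohort", {
  syn <- synapse_params(onset_latency_mean_ms = 4.5, onset_latency_sd_ms = 0.5)
  coh <- simulate_psc_cohort(12, syn, seed = 21)
  lat <- vapply(coh$neurons, function(tr) {
    measure_psc(tr, trace_meta(tr[[1]])$pulse_times_ms, "EPSC")$mean_latency_ms
  }, numeric(1))
  expect_lt(abs(mean(lat) - 4.5), 0.3)
})

test_that("psc measurement is invariant to trial order", {
  trials <- simulate_psc_train(synapse_params(n_pulses = 3), seed = 2)
  p <- trace_meta(trials[[1]])$pulse_times_ms
  a <- measure_psc(trials, p, "EPSC")
  b <- measure_psc(rev(trials), p, "EPSC")
  expect_equal(a$charge_pc, b$charge_pc)
  expect_equal(a$latencies[[1]], b$latencies[[1]])
})

test_that("psp amplitude reads the averaged deflection over baseline", {
  skhz <- 10
  t <- seq(0, 300, by = 1 / skhz)
  mk <- function(amp) {
    v <- -70 + ifelse(t >= 150 & t < 200, amp, 0)
    cc_trace(t, v, rep(0, length(t)), skhz)
  }
  m <- measure_psp(list(mk(5), mk(5), mk(5)), stim_times_ms = 150)
  expect_equal(m$amplitude_mv, 5)
  expect_identical(m$activation_class, "activated")
  z <- measure_psp(list(mk(0)), stim_times_ms = 150)
  expect_equal(z$amplitude_mv, 0)
  expect_identical(z$activation_class, "none")
  # Averaging first: two trials at 2 and 8 mV average to 5 mV.
  m2 <- measure_psp(list(mk(2), mk(8)), stim_times_ms = 150)
  expect_equal(m2$amplitude_mv, 5)
})

test_that("psp baseline must precede the stimulus", {
  t <- seq(0, 100, by = 0.1)
  tr <- cc_trace(t, rep(-70, length(t)), rep(0, length(t)), 10)
  expect_error(measure_psp(list(tr), stim_times_ms = 20,
                           baseline_window_ms = 50), "before the trace")
})

test_that("inhibition fraction is bounded and symmetric", {
  expect_equal(inhibition_fraction(1, 0), 1)
  expect_equal(inhibition_fraction(2, 2), 0.5)
  expect_equal(inhibition_fraction(1, 3), 0.25)
  expect_error(inhibition_fraction(0, 0), "undefined")
  for (k in 1:20) {
    i <- runif(1, 0, 50)
    e <- runif(1, 0, 50)
    f <- inhibition_fraction(i, e)
    expect_gte(f, 0)
    expect_lte(f, 1)
    expect_equal(inhibition_fraction(e, i), 1 - f, tolerance = 1e-12)
  }
})
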