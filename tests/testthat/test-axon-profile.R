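test_that("background subtraction clamps at zero", {
  pr <- generate_axon_profile(c(L6 = 1), background_au = 10, noise_sd_au = 0,
                              seed = 1)
  same <- subtract_background(pr, 0)
  expect_equal(same$intensity_au, pr$intensity_au)
  sub <- subtract_background(pr, 1e6)
  expect_true(all(sub$intensity_au == 0))
  expect_true(all(subtract_background(pr, 10)$intensity_au >= 0))
})

test_that("peak normalization is exact, scale-invariant and idempotent", {
  pr <- generate_axon_profile(c(L5 = 1), noise_sd_au = 0, background_au = 0,
                              seed = 2)
  n1 <- normalize_to_peak(pr)
  expect_equal(max(n1$intensity_au), 1)
  doubled <- pr
  doubled$intensity_au <- doubled$intensity_au * 2
  expect_equal(normalize_to_peak(doubled)$intensity_au, n1$intensity_au)
  expect_equal(normalize_to_peak(n1)$intensity_au, n1$intensity_au)
  zero <- subtract_background(pr, 1e9)
  expect_error(normalize_to_peak(zero), "All-zero")
})

test_that("layer fractions integrate to 100 and scale with layer width", {
  pr <- generate_axon_profile(c(L1 = 0.3, L4 = 0.3, L6 = 0.4),
                              noise_sd_au = 0, background_au = 0, seed = 3)
  frac <- layer_fractions(pr)
  expect_equal(sum(frac$fraction_pct), 100, tolerance = 1e-6)

  # Uniform intensity: fractions proportional to widths.
  tab <- layer_table()
  depth <- seq(0, 850, by = 1)
  unif <- circuitmapr:::new_axon_profile(depth, rep(2, length(depth)), tab)
  f <- layer_fractions(unif, tab)
  widths <- tab$lower_um - tab$upper_um
  expect_equal(f$fraction_pct, widths / sum(widths) * 100, tolerance = 0.3)
})

test_that("peak depth is rescaled to the layer extent", {
  tab <- layer_table()
  depth <- seq(0, 850, by = 1)
  mk <- function(peak_um) {
    i <- stats::dnorm(depth, peak_um, 15)
    circuitmapr:::new_axon_profile(depth, i, tab)
  }
  expect_equal(peak_depth_in_layer(mk(600), "L6"), 0, tolerance = 0.5)
  expect_equal(peak_depth_in_layer(mk(725), "L6"), 50, tolerance = 1)
  # Upper- vs lower-half peaks keep their ordering.
  upper <- peak_depth_in_layer(mk(470), "L5")
  lower <- peak_depth_in_layer(mk(560), "L5")
  expect_lt(upper, lower)
  expect_error(peak_depth_in_layer(mk(100), "L9"), "Unknown layer")
})

test_that("fractions are stable under 2x grid refinement", {
  targets <- c(L1 = 0.13, `L2/3` = 0.12, L4 = 0.12, L5 = 0.13, L6 = 0.50)
  coarse <- generate_axon_profile(targets, grid_um = 2, noise_sd_au = 0,
                                  background_au = 0, seed = 4)
  fine <- generate_axon_profile(targets, grid_um = 1, noise_sd_au = 0,
                                background_au = 0, seed = 4)
  fc <- layer_fractions(coarse)
  ff <- layer_fractions(fine)
  expect_true(all(abs(fc$fraction_pct - ff$fraction_pct) < 0.5))
})
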