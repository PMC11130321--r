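test_that("layer assignment uses half-open intervals", {
  expect_identical(assign_layer(50), "L1")
  expect_identical(assign_layer(430), "L5")  # exactly on the L4/L5 bound
  expect_identical(assign_layer(c(0, 100, 309.9, 849)),
                   c("L1", "L2/3", "L2/3", "L6"))
  expect_error(assign_layer(850), "Depths")
  expect_error(assign_layer(-1), "Depths")
})

test_that("activation classes follow the 3/7 mV criteria and are monotone", {
  expect_identical(classify_activation(c(2, 5, 8)),
                   c("none", "activated", "strong"))
  expect_identical(classify_activation(3), "none")   # strict >
  expect_identical(classify_activation(7), "activated")
  amps <- seq(0, 12, by = 0.5)
  cls <- classify_activation(amps)
  ord <- c(none = 0, activated = 1, strong = 2)
  expect_true(all(diff(ord[cls]) >= 0))
})

test_that("input matrices aggregate by layer and cell class", {
  rec <- tibble::tibble(layer = "L6", cell_class = "Pyr",
                        input_source = "V2M", amplitude_mv = 5)
  m <- assemble_input_matrix(rec, "V2M")
  expect_identical(nrow(m), 1L)
  expect_equal(m$mean_amplitude_mv, 5)
  expect_identical(m$activation_class, "activated")

  # Duplicating records doubles n but not the mean.
  m2 <- assemble_input_matrix(dplyr::bind_rows(rec, rec), "V2M")
  expect_equal(m2$mean_amplitude_mv, 5)
  expect_identical(m2$n, 2L)
})

test_that("matrix assembly is invariant to record order and batch splits", {
  set.seed(3)
  rec <- tibble::tibble(
    layer = sample(c("L2/3", "L5", "L6"), 30, replace = TRUE),
    cell_class = sample(c("Pyr", "PV"), 30, replace = TRUE),
    input_source = "LP",
    amplitude_mv = runif(30, 0, 10)
  )
  a <- assemble_input_matrix(rec, "LP")
  b <- assemble_input_matrix(rec[sample(30), ], "LP")
  expect_equal(a, b)
})

test_that("normalization maps the reference to 1 and is idempotent", {
  rec <- tibble::tibble(
    layer = c("L5", "L5", "L2/3"), cell_class = c("Pyr", "PV", "Pyr"),
    input_source = "LP", amplitude_mv = c(8, 4, 2)
  )
  m <- assemble_input_matrix(rec, "LP") |>
    normalize_strengths("L5", "Pyr")
  expect_equal(m$normalized_amplitude[m$layer == "L5" & m$cell_class == "Pyr"], 1)
  expect_equal(m$normalized_amplitude[m$layer == "L5" & m$cell_class == "PV"], 0.5)
  m2 <- normalize_strengths(m, "L5", "Pyr")
  expect_equal(m2$normalized_amplitude, m$normalized_amplitude)
  expect_error(normalize_strengths(m, "L1", "Pyr"), "absent")
})

test_that("convergence percentages match the tallies", {
  mk <- function(n_both, n_a, n_b, n_neither) {
    n <- n_both + n_a + n_b + n_neither
    tibble::tibble(
      cell_id = rep(seq_len(n), each = 2),
      source = rep(c("A", "B"), n),
      value = c(rep(c(10, 10), n_both), rep(c(10, 0), n_a),
                rep(c(0, 10), n_b), rep(c(0, 0), n_neither))
    )
  }
  s <- convergence_stats(mk(37, 26, 0, 2), "A", "B", threshold = 1)
  expect_equal(s$pct, c(56.92308, 40, 0, 3.076923), tolerance = 1e-5)
  expect_identical(s$n, c(37L, 26L, 0L, 2L))
  expect_equal(sum(s$pct), 100, tolerance = 0.2)
  expect_identical(attr(s, "n_total"), 65L)

  all_both <- convergence_stats(mk(10, 0, 0, 0), "A", "B", threshold = 1)
  expect_equal(all_both$pct, c(100, 0, 0, 0))
  none <- convergence_stats(mk(10, 0, 0, 0), "A", "B", threshold = 100)
  expect_equal(none$pct, c(0, 0, 0, 100))
})

test_that("convergence requires both sources per neuron", {
  bad <- tibble::tibble(cell_id = c(1, 1, 2), source = c("A", "B", "A"),
                        value = c(1, 1, 1))
  expect_error(convergence_stats(bad, "A", "B", threshold = 0.5), "both sources")
})
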