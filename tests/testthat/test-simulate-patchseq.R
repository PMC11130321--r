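test_that("a spec without planted failures passes QC everywhere", {
  sim <- generate_patchseq_counts(patchseq_spec(
    n_cells = 30, n_genes = 300, n_low_depth_cells = 0,
    n_contaminated_cells = 0, seed = 2))
  qc <- qc_cells(sim$counts)
  expect_true(all(qc$verdict == "pass"))
})

test_that("the 91-cell fixture yields exactly 80 QC survivors", {
  sim <- patchseq_fixture_v1()
  qc <- qc_cells(sim$counts)
  expect_identical(sum(qc$verdict == "pass"), 80L)
  expect_identical(sum(qc$verdict == "fail_low_depth"), 4L)
  expect_identical(sum(qc$verdict == "fail_inhibitory"), 7L)
  # Verdicts agree with the planted truth.
  expect_identical(qc$verdict == "fail_low_depth", sim$truth$planted_low_depth)
  expect_identical(qc$verdict == "fail_inhibitory",
                   sim$truth$planted_contaminated)
})

test_that("generation is deterministic and counts are nonnegative integers", {
  spec <- patchseq_spec(n_cells = 25, n_genes = 250, seed = 4,
                        n_low_depth_cells = 2, n_contaminated_cells = 3)
  a <- generate_patchseq_counts(spec)
  b <- generate_patchseq_counts(spec)
  expect_identical(a$counts, b$counts)
  expect_true(is.integer(a$counts))
  expect_true(all(a$counts >= 0))
})

test_that("infeasible specs are rejected", {
  expect_error(patchseq_spec(n_genes = 10), "marker panels")
  expect_error(patchseq_spec(n_cells = 5, n_low_depth_cells = 3,
                             n_contaminated_cells = 3), "exceed")
})

test_that("contaminated cells outscore clean cells on the inhibitory panel only", {
  sim <- patchseq_fixture_v1()
  summ <- marker_panel_summary(sim$counts)
  inh <- summ[summ$panel == "inhibitory", ]
  contaminated <- sim$truth$planted_contaminated
  expect_gt(min(inh$mean_log2[contaminated]),
            max(inh$mean_log2[!contaminated & !sim$truth$planted_low_depth]))
  exc <- summ[summ$panel == "excitatory", ]
  keep <- !sim$truth$planted_low_depth
  expect_gt(mean(exc$mean_log2[keep]), mean(inh$mean_log2[keep & !contaminated]))
})
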