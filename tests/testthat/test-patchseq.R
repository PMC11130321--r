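test_that("log transform maps counts as log2(x + 1)", {
  expect_equal(log_transform(matrix(c(0, 7, 1), 1)), matrix(c(0, 3, 1), 1))
  x <- matrix(0:20, 3)
  expect_true(all(diff(as.vector(log_transform(x))) > 0)) # monotone
  expect_equal(2^log_transform(x) - 1, x)                 # invertible
  expect_error(log_transform(matrix(-1)), "nonnegative")
})

test_that("QC thresholds and precedence behave as specified", {
  genes <- c("Slc32a1", "Gad1", "Gad2", "Actb")
  mk <- function(...) {
    m <- cbind(...)
    rownames(m) <- genes
    colnames(m) <- sprintf("c%d", seq_len(ncol(m)))
    m
  }
  # Cell 1: total 499 -> low depth. Cell 2: markers (7,7,7): log2 sum 9 ->
  # inhibitory. Cell 3: clean. Cell 4: fails both -> low depth wins.
  m <- mk(c(0, 0, 0, 499), c(7, 7, 7, 1000), c(0, 0, 0, 800), c(7, 7, 7, 100))
  qc <- qc_cells(m)
  expect_identical(qc$verdict,
                   c("fail_low_depth", "fail_inhibitory", "pass", "fail_low_depth"))
  expect_equal(qc$inhibitory_marker_log2_sum[2], 9)
  expect_error(qc_cells(m[1:2, , drop = FALSE]), "missing")
})

test_that("QC is idempotent on the passing subset", {
  sim <- patchseq_fixture_v1()
  qc1 <- qc_cells(sim$counts)
  passing <- sim$counts[, qc1$verdict == "pass", drop = FALSE]
  qc2 <- qc_cells(passing)
  expect_true(all(qc2$verdict == "pass"))
  expect_equal(qc2$total_counts,
               qc1$total_counts[qc1$verdict == "pass"])
})

test_that("gene gating counts expressing cells against both thresholds", {
  m <- rbind(
    kept = c(rep(5, 10), rep(0, 10)),     # >= 5 in exactly 10 cells
    dropped = c(rep(5, 9), rep(0, 11)),   # 9 cells: excluded
    zero = rep(0, 20),
    high = c(rep(4, 20))                  # never reaches count 5
  )
  colnames(m) <- sprintf("c%d", 1:20)
  g <- gene_gate(m)
  expect_identical(g$retained, c(TRUE, FALSE, FALSE, FALSE))
  # Raising either threshold never adds genes.
  g2 <- gene_gate(m, min_cells = 11)
  g3 <- gene_gate(m, min_count = 6)
  expect_true(all(g2$retained <= g$retained))
  expect_true(all(g3$retained <= g$retained))
})

test_that("DEG calls partition genes by the q and fold-change thresholds", {
  stats <- tibble::tibble(
    gene = c("Hcn1", "g2", "g3", "g4"),
    log2fc = c(3.8, 0.8, 4, -2.5),
    q_value = c(0.03, 0.001, 0.06, 0.01)
  )
  called <- call_degs(stats)
  expect_identical(called$call, c("up_a", "not_de", "not_de", "up_b"))
  expect_setequal(unique(called$call), c("up_a", "not_de", "up_b"))
  expect_error(call_degs(dplyr::mutate(stats, q_value = c(2, 0, 0, 0))),
               "0, 1")
})

test_that("the rank-sum engine is calibrated under the null", {
  set.seed(31)
  m <- matrix(rnbinom(200 * 60, mu = 20, size = 2), nrow = 200,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("c%02d", 1:60)))
  labels <- rep(c("a", "b"), each = 30)
  res <- de_test(m, labels)
  expect_lt(mean(res$q_value < 0.05), 0.02)
  # BH never decreases a p value and q is monotone in p.
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
})

test_that("a planted 8-fold shift is detected with the right direction", {
  set.seed(32)
  m <- matrix(rnbinom(100 * 80, mu = 20, size = 2), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("c%02d", 1:80)))
  labels <- rep(c("a", "b"), each = 40)
  m["g001", labels == "a"] <- rnbinom(40, mu = 160, size = 2)
  called <- call_degs(de_test(m, labels))
  expect_identical(called$call[called$gene == "g001"], "up_a")
  # Permuting labels destroys the call set.
  perm <- call_degs(de_test(m, sample(labels)))
  expect_lte(sum(perm$call != "not_de"), 2)
})

test_that("marker panel summaries reduce to the transformed values", {
  m <- matrix(c(7, 0, 3, 0), nrow = 2,
              dimnames = list(c("Actb", "Gad1"), c("c1", "c2")))
  s <- marker_panel_summary(m, list(one = "Actb", two = c("Actb", "Gad1")))
  expect_equal(s$mean_log2[s$panel == "one"], c(3, 2))
  expect_equal(s$mean_log2[s$panel == "two" & s$cell_id == "c1"], (3 + 0) / 2)
  zero <- matrix(0, 2, 1, dimnames = list(c("Actb", "Gad1"), "c1"))
  sz <- marker_panel_summary(zero, list(p = c("Actb", "Gad1")))
  expect_equal(sz$mean_log2, 0)
  expect_error(marker_panel_summary(m, list(p = character(0))), "nonempty")
})
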