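#' Log-transform a count matrix
#'
#' Elementwise `log2(x + 1)` of nonnegative counts.
#'
#' @param counts Gene-by-cell matrix of nonnegative counts.
#' @return Matrix of the same shape.
#' @examples
#' log_transform(matrix(c(0, 7), 1))
#' @export
log_transform <- function(counts) {
  if (any(counts < 0)) abort("Counts must be nonnegative.")
  log2(counts + 1)
}

#' Two-stage Patch-seq cell quality control
#'
#' Stage one excludes failed libraries: cells whose summed counts across
#' all genes fall below the depth floor (500). Stage two excludes
#' GABAergic-contaminated cells among the survivors: cells whose summed
#' `log2(x + 1)` expression of the three inhibitory marker genes exceeds
#' the ceiling (7). Low depth takes precedence — a cell failing both is
#' reported as `fail_low_depth`.
#'
#' @param counts Gene-by-cell count matrix with gene names as rownames.
#' @param inhibitory_markers The three inhibitory marker genes.
#' @param depth_floor Library-size floor (counts).
#' @param marker_ceiling Inhibitory-marker log2-sum ceiling.
#'
#' @return A tibble (one row per cell): `cell_id`, `total_counts`,
#'   `inhibitory_marker_log2_sum`, `verdict` (`pass`, `fail_low_depth`,
#'   `fail_inhibitory`). Thresholds are attached as attributes.
#' @examples
#' sim <- patchseq_fixture_v1()
#' table(qc_cells(sim$counts)$verdict)
#' @export
qc_cells <- function(counts,
                     inhibitory_markers = default_marker_panels()$inhibitory,
                     depth_floor = 500,
                     marker_ceiling = 7) {
  if (is.null(rownames(counts))) abort("`counts` needs gene rownames.")
  missing <- setdiff(inhibitory_markers, rownames(counts))
  if (length(missing)) {
    abort(sprintf("Marker gene(s) missing from the matrix: %s.",
                  paste(missing, collapse = ", ")))
  }
  total <- colSums(counts)
  inh_sum <- colSums(log_transform(counts[inhibitory_markers, , drop = FALSE]))
  verdict <- dplyr::case_when(
    total < depth_floor ~ "fail_low_depth",
    inh_sum > marker_ceiling ~ "fail_inhibitory",
    TRUE ~ "pass"
  )
  out <- tibble(
    cell_id = colnames(counts) %||% sprintf("cell%03d", seq_along(total)),
    total_counts = unname(total),
    inhibitory_marker_log2_sum = unname(inh_sum),
    verdict = verdict
  )
  attr(out, "thresholds") <- list(depth_floor = depth_floor,
                                  marker_ceiling = marker_ceiling,
                                  inhibitory_markers = inhibitory_markers)
  out
}

#' Gene gating by expression prevalence
#'
#' Retains genes "expressed" — count at or above `min_count` (5) — in at
#' least `min_cells` cells (10). Run after cell QC, on the passing cells
#' only.
#'
#' @param counts Gene-by-cell count matrix (QC-passing cells).
#' @param min_cells Minimum number of expressing cells.
#' @param min_count Count at which a gene is called expressed in a cell.
#' @return A tibble: `gene`, `n_expressing_cells`, `retained`.
#' @export
gene_gate <- function(counts, min_cells = 10, min_count = 5) {
  n_exp <- rowSums(counts >= min_count)
  tibble(
    gene = rownames(counts) %||% sprintf("gene%05d", seq_along(n_exp)),
    n_expressing_cells = unname(n_exp),
    retained = unname(n_exp) >= min_cells
  )
}

#' Per-panel marker expression summary
#'
#' Mean `log2(x + 1)` expression of each marker panel in each cell — the
#' sampling-specificity check run before differential expression.
#'
#' @param counts Gene-by-cell count matrix.
#' @param panels Named list of marker-gene character vectors.
#' @return A tibble: `cell_id`, `panel`, `mean_log2`.
#' @export
marker_panel_summary <- function(counts, panels = default_marker_panels()) {
  if (!length(panels) || any(lengths(panels) == 0L)) {
    abort("All panels must be nonempty.")
  }
  lt <- log_transform(counts)
  cells <- colnames(counts) %||% sprintf("cell%03d", seq_len(ncol(counts)))
  purrr::imap(panels, function(genes, nm) {
    missing <- setdiff(genes, rownames(counts))
    if (length(missing)) {
      abort(sprintf("Panel '%s' gene(s) missing: %s.", nm,
                    paste(missing, collapse = ", ")))
    }
    tibble(cell_id = cells, panel = nm,
           mean_log2 = unname(colMeans(lt[genes, , drop = FALSE])))
  }) |>
    dplyr::bind_rows()
}

#' Rank-sum differential-expression engine
#'
#' The bundled two-class test: per gene, a two-sided Wilcoxon rank-sum
#' test on `log2(x + 1)` values, Benjamini–Hochberg adjustment across
#' genes, and a fold change from the back-transformed class means of the
#' log values (`log2FC > 0` means higher in class A). The engine is
#' deliberately pluggable: [call_degs()] accepts any per-gene
#' `(log2fc, q_value)` table, so statistics computed by an external
#' shrinkage-based engine can be gated identically.
#'
#' @param counts Gene-by-cell count matrix (gated genes, QC-passing
#'   cells).
#' @param labels Per-cell class labels (two classes, >= 3 cells each).
#' @param class_a Which label is class A (the log2FC numerator);
#'   default the first sorted label.
#' @return A tibble: `gene`, `log2fc`, `p_value`, `q_value`.
#' @export
de_test <- function(counts, labels, class_a = NULL) {
  labels <- as.character(labels)
  if (length(labels) != ncol(counts)) {
    abort("`labels` must have one entry per cell.")
  }
  classes <- sort(unique(labels))
  if (length(classes) != 2L) abort("Exactly two classes are required.")
  class_a <- class_a %||% classes[1]
  class_b <- setdiff(classes, class_a)
  if (min(table(labels)) < 3L) abort("Each class needs at least 3 cells.")

  lt <- log_transform(counts)
  a <- labels == class_a
  p <- vapply(seq_len(nrow(lt)), function(g) {
    va <- lt[g, a]
    vb <- lt[g, !a]
    if (all(va == va[1]) && all(vb == vb[1]) && va[1] == vb[1]) return(1)
    suppressWarnings(wilcox.test(va, vb, exact = FALSE)$p.value)
  }, numeric(1))
  mean_a <- rowMeans(lt[, a, drop = FALSE])
  mean_b <- rowMeans(lt[, !a, drop = FALSE])
  # Back-transform the log-scale class means to a fold change, with a
  # pseudocount of 1 guarding silent genes.
  log2fc <- log2((2^mean_a - 1 + 1) / (2^mean_b - 1 + 1))
  tibble(
    gene = rownames(counts) %||% sprintf("gene%05d", seq_len(nrow(counts))),
    log2fc = unname(log2fc),
    p_value = p,
    q_value = p.adjust(p, method = "BH")
  )
}

#' Call differentially expressed genes
#'
#' Thresholds a per-gene statistics table: a gene is a DEG when
#' `q < q_max` (0.05) and its fold change exceeds `fc_min` (2) in either
#' direction, i.e. `|log2fc| > log2(fc_min)`. Genes are partitioned into
#' exactly three classes: `up_a`, `up_b`, `not_de`.
#'
#' @param stats A tibble with columns `gene`, `log2fc`, `q_value` (as from
#'   [de_test()] or an external engine).
#' @param q_max Adjusted-significance ceiling.
#' @param fc_min Fold-change floor (linear scale).
#' @return `stats` with an added `call` column; thresholds attached as
#'   attributes.
#' @examples
#' call_degs(tibble::tibble(gene = "Hcn1", log2fc = 3.8, q_value = 0.03))
#' @export
call_degs <- function(stats, q_max = 0.05, fc_min = 2) {
  if (!all(c("gene", "log2fc", "q_value") %in% names(stats))) {
    abort("`stats` needs columns gene, log2fc, q_value.")
  }
  if (any(stats$q_value < 0 | stats$q_value > 1, na.rm = TRUE)) {
    abort("q values must lie in [0, 1].")
  }
  lfc_min <- log2(fc_min)
  out <- dplyr::mutate(stats, call = dplyr::case_when(
    .data$q_value < q_max & .data$log2fc > lfc_min ~ "up_a",
    .data$q_value < q_max & .data$log2fc < -lfc_min ~ "up_b",
    TRUE ~ "not_de"
  ))
  attr(out, "thresholds") <- list(q_max = q_max, fc_min = fc_min)
  out
}
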