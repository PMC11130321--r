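#' Marker-gene panels for Patch-seq quality control
#'
#' The four panels used to assess sampling specificity: pan-neuronal,
#' cortical excitatory, GABAergic inhibitory and glial marker genes. The
#' inhibitory panel (Slc32a1, Gad1, Gad2) is the one whose summed
#' log2(x+1) expression defines the contamination ceiling.
#'
#' @return Named list of character vectors.
#' @export
default_marker_panels <- function() {
  list(
    pan_neuronal = c("Actb", "Syt4", "Atp1a3", "Syt1", "Calm1", "Arpp21", "Snap25"),
    excitatory = c("Gria2", "Camk2a", "Slc17a7"),
    inhibitory = c("Slc32a1", "Gad1", "Gad2"),
    glial = c("Adarb2", "Gfap", "Aqp4", "Mlc1")
  )
}

#' Specification for a synthetic Patch-seq count matrix
#'
#' Describes a gene-by-cell negative-binomial count matrix that emulates
#' Smart-seq2 Patch-seq output from excitatory cortical neurons: deep
#' libraries for most cells, a planted subset of failed (low-depth)
#' libraries, and a planted subset of cells contaminated by inhibitory-
#' neuron transcripts. The generator guarantees the planted QC structure
#' exactly: `n_low_depth_cells` cells fall below the 500-count library
#' floor, and `n_contaminated_cells` of the remaining cells exceed the
#' inhibitory-marker log2-sum ceiling of 7.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param class_labels Per-cell class labels (recycled); default an even
#'   split of `"Pyr_LP"` / `"Pyr_ORBvl"`.
#' @param marker_panels Named list of marker panels (must be disjoint and
#'   fit in `n_genes`).
#' @param n_low_depth_cells Cells whose library is forced below the QC
#'   floor.
#' @param n_contaminated_cells Cells (among the remainder) whose
#'   inhibitory-marker expression is forced above the QC ceiling.
#' @param mean_total_counts Expected library size of a healthy cell.
#' @param dispersion Negative-binomial overdispersion (NB `size` =
#'   `1/dispersion`).
#' @param n_de_genes Number of filler genes given a class-dependent mean
#'   shift (half up in each class), for differential-expression exercises.
#' @param de_fold Fold change applied to those genes.
#' @param seed Integer seed; generation is deterministic given the spec.
#'
#' @return A list with class `"patchseq_spec"`.
#' @export
patchseq_spec <- function(n_cells = 91,
                          n_genes = 3000,
                          class_labels = NULL,
                          marker_panels = default_marker_panels(),
                          n_low_depth_cells = 4,
                          n_contaminated_cells = 7,
                          mean_total_counts = 2e5,
                          dispersion = 0.4,
                          n_de_genes = 0,
                          de_fold = 4,
                          seed = 1) {
  check_number(n_cells, "n_cells", min = 1)
  check_number(n_genes, "n_genes", min = 1)
  check_number(n_low_depth_cells, "n_low_depth_cells", min = 0)
  check_number(n_contaminated_cells, "n_contaminated_cells", min = 0)
  if (n_low_depth_cells + n_contaminated_cells > n_cells) {
    abort("Planted low-depth plus contaminated cells exceed `n_cells`.")
  }
  markers <- unlist(marker_panels, use.names = FALSE)
  if (anyDuplicated(markers)) abort("Marker panels must be disjoint.")
  if (length(markers) > n_genes) {
    abort("`n_genes` is smaller than the union of the marker panels.")
  }
  if (is.null(class_labels)) {
    class_labels <- rep(c("Pyr_LP", "Pyr_ORBvl"), length.out = n_cells)
  }
  class_labels <- rep(class_labels, length.out = n_cells)
  check_number(dispersion, "dispersion", min = 0, strict_min = TRUE)
  check_number(n_de_genes, "n_de_genes", min = 0)
  check_number(de_fold, "de_fold", min = 1)
  structure(
    list(
      n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
      class_labels = class_labels, marker_panels = marker_panels,
      n_low_depth_cells = as.integer(n_low_depth_cells),
      n_contaminated_cells = as.integer(n_contaminated_cells),
      mean_total_counts = mean_total_counts, dispersion = dispersion,
      n_de_genes = as.integer(n_de_genes), de_fold = de_fold,
      seed = seed
    ),
    class = "patchseq_spec"
  )
}

#' Generate a synthetic Patch-seq count matrix
#'
#' Draws gene-by-cell counts from a negative-binomial model (per-gene
#' log-normal base means, per-cell library-size factors, class-dependent
#' shifts for the designated differential genes) and then plants the QC
#' structure of the spec exactly: designated low-depth cells are scaled
#' below the 500-count floor, designated contaminated cells have their
#' three inhibitory markers raised above the log2-sum ceiling of 7, and
#' all other cells are kept clean of both failure modes.
#'
#' @param spec A [patchseq_spec()].
#' @return A list: `counts` (integer matrix, genes x cells, dimnames set),
#'   `truth` (tibble with `cell_id`, `class`, `planted_low_depth`,
#'   `planted_contaminated`), and `spec`.
#' @examples
#' sim <- generate_patchseq_counts(patchseq_spec(n_cells = 20, n_genes = 200))
#' dim(sim$counts)
#' @export
generate_patchseq_counts <- function(spec) {
  stopifnot(inherits(spec, "patchseq_spec"))
  markers <- unlist(spec$marker_panels, use.names = FALSE)
  n_filler <- spec$n_genes - length(markers)
  genes <- c(markers, sprintf("gene%05d", seq_len(n_filler)))
  cells <- sprintf("cell%03d", seq_len(spec$n_cells))
  classes <- unique(spec$class_labels)

  with_local_seed(spec$seed, {
    base_mu <- stats::rlnorm(spec$n_genes, meanlog = log(20), sdlog = 1.4)
    names(base_mu) <- genes
    # Marker expression levels reflect excitatory cortical neurons:
    # strong neuronal and excitatory markers, near-silent inhibitory and
    # glial markers.
    base_mu[spec$marker_panels$pan_neuronal] <- stats::rlnorm(
      length(spec$marker_panels$pan_neuronal), log(400), 0.3)
    base_mu[spec$marker_panels$excitatory] <- stats::rlnorm(
      length(spec$marker_panels$excitatory), log(250), 0.3)
    base_mu[spec$marker_panels$inhibitory] <- 0.05
    base_mu[spec$marker_panels$glial] <- 0.5

    # Class-dependent fold shifts for the designated DE genes.
    lfc <- stats::setNames(numeric(spec$n_genes), genes)
    if (spec$n_de_genes > 0) {
      if (spec$n_de_genes > n_filler) abort("More DE genes than filler genes.")
      de_genes <- sprintf("gene%05d", seq_len(spec$n_de_genes))
      half <- ceiling(spec$n_de_genes / 2)
      lfc[de_genes[seq_len(half)]] <- log2(spec$de_fold)
      lfc[de_genes[-seq_len(half)]] <- -log2(spec$de_fold)
    }

    # Library-size factors; normalize base means to the target library.
    sf <- stats::rlnorm(spec$n_cells, 0, 0.25)
    scale_to_lib <- spec$mean_total_counts / sum(base_mu)

    is_class_a <- spec$class_labels == classes[1]
    size <- 1 / spec$dispersion
    counts <- matrix(0L, nrow = spec$n_genes, ncol = spec$n_cells,
                     dimnames = list(genes, cells))
    for (j in seq_len(spec$n_cells)) {
      mu_j <- base_mu * scale_to_lib * sf[j] *
        2^(if (is_class_a[j]) lfc else -lfc)
      counts[, j] <- rnbinom(spec$n_genes, mu = mu_j, size = size)
    }

    low_idx <- seq_len(spec$n_low_depth_cells)
    contam_idx <- spec$n_low_depth_cells + seq_len(spec$n_contaminated_cells)

    # Plant low-depth failures: scale the library below the floor.
    for (j in low_idx) {
      target <- sample(150:400, 1)
      tot <- sum(counts[, j])
      counts[, j] <- as.integer(floor(counts[, j] * target / max(tot, 1)))
      stopifnot(sum(counts[, j]) < 500)
    }
    # Plant inhibitory contamination: raise the three markers well above
    # the ceiling (counts ~ tens to hundreds).
    inh <- spec$marker_panels$inhibitory
    for (j in contam_idx) {
      counts[inh, j] <- as.integer(rnbinom(length(inh), mu = 120, size = 5) + 20L)
    }
    # Keep every other cell clean of both failure modes.
    clean_idx <- setdiff(seq_len(spec$n_cells), c(low_idx, contam_idx))
    for (j in clean_idx) {
      if (sum(counts[, j]) < 500) {
        counts[1, j] <- counts[1, j] + 500L
      }
      if (sum(log2(counts[inh, j] + 1)) > 7) {
        counts[inh, j] <- 0L
      }
    }
    for (j in contam_idx) {
      stopifnot(sum(counts[, j]) >= 500, sum(log2(counts[inh, j] + 1)) > 7)
    }

    storage.mode(counts) <- "integer"
    truth <- tibble(
      cell_id = cells,
      class = spec$class_labels,
      planted_low_depth = seq_len(spec$n_cells) %in% low_idx,
      planted_contaminated = seq_len(spec$n_cells) %in% contam_idx
    )
    list(counts = counts, truth = truth, spec = spec)
  })
}

#' The packaged 91-cell Patch-seq fixture
#'
#' The reference synthetic cohort used throughout the worked examples:
#' 91 cells, 4 planted low-depth libraries and 7 planted inhibitory-
#' contaminated cells (seed 7), so the two-stage quality control passes
#' exactly 80 cells.
#'
#' @return As [generate_patchseq_counts()].
#' @export
patchseq_fixture_v1 <- function() {
  generate_patchseq_counts(patchseq_spec(
    n_cells = 91, n_genes = 3000,
    n_low_depth_cells = 4, n_contaminated_cells = 7,
    n_de_genes = 40, de_fold = 4,
    seed = 7
  ))
}
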