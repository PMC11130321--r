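#' Read and write trace files
#'
#' Traces travel as delimited text: `#`-prefixed header lines carry the
#' protocol as `key=value` pairs (plus one JSON line for free-form
#' metadata), followed by a CSV body of `time_ms` and the signal
#' column(s). The format round-trips both trace classes exactly.
#'
#' @param trace A [vc_trace()] or [cc_trace()].
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` the
#'   reconstructed trace.
#' @examples
#' tr <- simulate_voltage_clamp_step(seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_trace(tr, f)
#' identical(dim(read_trace(f)), dim(tr))
#' @export
write_trace <- function(trace, path) {
  p <- trace_protocol(trace)
  header <- c(
    sprintf("# kind=%s", p$kind),
    sprintf("# sampling_khz=%.10g", p$sampling_khz),
    if (!is.null(p$step_onset_ms) && is.finite(p$step_onset_ms)) {
      c(sprintf("# step_onset_ms=%.10g", p$step_onset_ms),
        sprintf("# step_dv_mv=%.10g", p$step_dv_mv),
        sprintf("# step_duration_ms=%.10g", p$step_duration_ms))
    },
    if (!is.null(p$holding_potential_mv)) {
      sprintf("# holding_potential_mv=%.10g", p$holding_potential_mv)
    },
    sprintf("# meta=%s", jsonlite::toJSON(trace_meta(trace),
                                          auto_unbox = TRUE, digits = NA))
  )
  writeLines(header, path)
  readr::write_csv(as_tibble(as.data.frame(trace)), path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    key <- sub("^# ([^=]+)=.*$", "\\1", h)
    val <- sub("^# [^=]+=", "", h)
    kv[[key]] <- val
  }
  meta <- if (!is.null(kv$meta)) jsonlite::fromJSON(kv$meta) else list()
  body <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  num <- function(k, default = NA_real_) {
    if (is.null(kv[[k]])) default else as.numeric(kv[[k]])
  }
  if (identical(kv$kind, "current_clamp")) {
    cc_trace(body$time_ms, body$voltage_mv, body$injected_pa,
             sampling_khz = num("sampling_khz"), meta = meta)
  } else {
    tr <- vc_trace(body$time_ms, body$current_pa,
                   sampling_khz = num("sampling_khz"),
                   step_onset_ms = num("step_onset_ms"),
                   step_dv_mv = num("step_dv_mv"),
                   step_duration_ms = num("step_duration_ms"),
                   holding_potential_mv = num("holding_potential_mv", -70),
                   meta = meta)
    attr(tr, "protocol")$kind <- kv$kind %||% "voltage_clamp"
    tr
  }
}

#' Read and write count matrices
#'
#' Matrix Market (`.mtx`) with sidecar `genes.tsv` / `cells.tsv` name
#' files — the standard sparse exchange layout — or dense tab-delimited
#' text with gene rownames.
#'
#' @param counts Gene-by-cell integer matrix with dimnames.
#' @param dir Directory for the MTX triplet (created if needed).
#' @return `write_counts_mtx()` returns `dir` invisibly;
#'   `read_counts_mtx()` the dense integer matrix with dimnames.
#' @export
write_counts_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "cells.tsv")))
  m
}

#' @rdname write_counts_mtx
#' @param path File path for the dense layout.
#' @export
write_counts_dense <- function(counts, path) {
  df <- as_tibble(as.data.frame(counts), rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_counts_mtx
#' @export
read_counts_dense <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene
  m
}

#' Read and write axon profiles
#'
#' Two-column tab-delimited text (`depth_um`, `intensity_au`).
#'
#' @param profile An `axon_profile`.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(tibble(depth_um = profile$depth_um,
                          intensity_au = profile$intensity_au), path)
  invisible(path)
}

#' @rdname write_profile
#' @param table A [layer_table()] to attach.
#' @export
read_profile <- function(path, table = layer_table()) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  new_axon_profile(df$depth_um, df$intensity_au, table)
}
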