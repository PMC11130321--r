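#' Pipeline configuration
#'
#' A validated bundle of every tunable threshold in the pipeline, with
#' the conventions used throughout: activation criteria 3/7 mV, Patch-seq
#' QC floor 500 counts and inhibitory-marker ceiling 7, DEG thresholds
#' q < 0.05 and fold change > 2, access-resistance limits 40 MΩ and 20%
#' drift, plus the layer table and a base seed. Unknown keys are
#' rejected — a typo must not silently fall back to a default.
#'
#' @param activation_mv,strong_mv EPSP activation thresholds, mV.
#' @param qc_depth_floor,qc_marker_ceiling Patch-seq QC thresholds.
#' @param deg_q_max,deg_fc_min DEG thresholds.
#' @param ra_limit_mohm,ra_max_rel_change Recording QC thresholds.
#' @param layer_boundaries_um Five layer floors for [layer_table()].
#' @param seed Base seed.
#' @return A list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config()
#' f <- tempfile(fileext = ".yaml")
#' write_config(cfg, f)
#' read_config(f)$deg_q_max
#' @export
pipeline_config <- function(activation_mv = 3, strong_mv = 7,
                            qc_depth_floor = 500, qc_marker_ceiling = 7,
                            deg_q_max = 0.05, deg_fc_min = 2,
                            ra_limit_mohm = 40, ra_max_rel_change = 0.20,
                            layer_boundaries_um = c(100, 310, 430, 600, 850),
                            seed = 1) {
  cfg <- list(
    activation_mv = activation_mv, strong_mv = strong_mv,
    qc_depth_floor = qc_depth_floor, qc_marker_ceiling = qc_marker_ceiling,
    deg_q_max = deg_q_max, deg_fc_min = deg_fc_min,
    ra_limit_mohm = ra_limit_mohm, ra_max_rel_change = ra_max_rel_change,
    layer_boundaries_um = layer_boundaries_um, seed = seed
  )
  validate_config(cfg)
}

config_keys <- function() {
  c("activation_mv", "strong_mv", "qc_depth_floor", "qc_marker_ceiling",
    "deg_q_max", "deg_fc_min", "ra_limit_mohm", "ra_max_rel_change",
    "layer_boundaries_um", "seed")
}

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_keys())
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(config_keys(), names(cfg))
  if (length(missing)) {
    abort(sprintf("Missing configuration key(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  for (k in setdiff(config_keys(), "layer_boundaries_um")) {
    check_number(cfg[[k]], k)
  }
  layer_table(cfg$layer_boundaries_um) # validates the boundaries
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}
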