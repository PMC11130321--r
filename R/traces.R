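#' Trace containers
#'
#' A trace is a tibble on a uniform time grid plus protocol attributes.
#' Voltage-clamp traces (`vc_trace`) carry `time_ms` and `current_pa`;
#' current-clamp traces (`cc_trace`) carry `time_ms`, `voltage_mv` and
#' `injected_pa`. Protocol fields (sampling rate, step geometry, holding
#' potential) live in `attr(x, "protocol")`; simulator ground truth, when
#' present, lives in `attr(x, "meta")` and is what oracle tests compare
#' against.
#'
#' @param time_ms Time grid in ms, uniform and increasing.
#' @param current_pa Clamp current in pA (signed; inward negative).
#' @param sampling_khz Sampling rate in kHz; must match the grid spacing.
#' @param step_onset_ms,step_dv_mv,step_duration_ms Voltage-step geometry.
#' @param holding_potential_mv Holding potential, mV.
#' @param meta Named list of free-form metadata (simulated ground truth).
#'
#' @return A tibble of class `vc_trace` or `cc_trace`.
#' @export
vc_trace <- function(time_ms, current_pa, sampling_khz,
                     step_onset_ms = NA_real_, step_dv_mv = NA_real_,
                     step_duration_ms = NA_real_,
                     holding_potential_mv = -70, meta = list()) {
  check_uniform_grid(time_ms, sampling_khz)
  if (length(current_pa) != length(time_ms)) {
    abort("`current_pa` and `time_ms` must have the same length.")
  }
  if (is.finite(step_onset_ms) &&
      (step_onset_ms < time_ms[1] || step_onset_ms > time_ms[length(time_ms)])) {
    abort("`step_onset_ms` must lie within the trace.")
  }
  out <- tibble(time_ms = time_ms, current_pa = current_pa)
  attr(out, "protocol") <- list(
    kind = "voltage_clamp",
    sampling_khz = sampling_khz,
    step_onset_ms = step_onset_ms,
    step_dv_mv = step_dv_mv,
    step_duration_ms = step_duration_ms,
    holding_potential_mv = holding_potential_mv
  )
  attr(out, "meta") <- meta
  class(out) <- c("vc_trace", class(out))
  out
}

#' @rdname vc_trace
#' @param voltage_mv Membrane voltage in mV.
#' @param injected_pa Injected current per sample, pA.
#' @export
cc_trace <- function(time_ms, voltage_mv, injected_pa, sampling_khz,
                     meta = list()) {
  check_uniform_grid(time_ms, sampling_khz)
  if (length(voltage_mv) != length(time_ms) ||
      length(injected_pa) != length(time_ms)) {
    abort("`voltage_mv`, `injected_pa` and `time_ms` must share a length.")
  }
  if (!all(is.finite(voltage_mv))) abort("`voltage_mv` must be finite.")
  out <- tibble(time_ms = time_ms, voltage_mv = voltage_mv,
                injected_pa = injected_pa)
  attr(out, "protocol") <- list(kind = "current_clamp",
                                sampling_khz = sampling_khz)
  attr(out, "meta") <- meta
  class(out) <- c("cc_trace", class(out))
  out
}

check_uniform_grid <- function(time_ms, sampling_khz) {
  check_number(sampling_khz, "sampling_khz", min = 0, strict_min = TRUE)
  if (length(time_ms) < 2L) abort("A trace needs at least two samples.")
  dt <- diff(time_ms)
  if (any(abs(dt - 1 / sampling_khz) > 1e-6)) {
    abort("`time_ms` must be a uniform grid matching `sampling_khz`.")
  }
  invisible(TRUE)
}

#' @rdname vc_trace
#' @param x A trace.
#' @export
trace_protocol <- function(x) attr(x, "protocol")

#' @rdname vc_trace
#' @export
trace_meta <- function(x) attr(x, "meta")

#' @export
print.vc_trace <- function(x, ...) {
  p <- trace_protocol(x)
  cat(sprintf("<vc_trace> %d samples @ %g kHz", nrow(x), p$sampling_khz))
  if (is.finite(p$step_onset_ms)) {
    cat(sprintf(", %+g mV step at %g ms for %g ms",
                p$step_dv_mv, p$step_onset_ms, p$step_duration_ms))
  }
  cat("\n")
  NextMethod()
}

#' @export
print.cc_trace <- function(x, ...) {
  p <- trace_protocol(x)
  cat(sprintf("<cc_trace> %d samples @ %g kHz\n", nrow(x), p$sampling_khz))
  NextMethod()
}
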