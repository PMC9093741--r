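#' Fluorescence trace container
#'
#' A fluorescence trace is a tibble with columns `time` (seconds) and `value`,
#' carrying the frame rate, the unit of `value` and an ROI identifier as
#' attributes. All photometry, event-detection and oscillation functions accept
#' and return this class so calls chain with the pipe.
#'
#' @param values Numeric vector of per-frame fluorescence values.
#' @param frame_rate Acquisition rate in frames per second.
#' @param unit One of `"counts"` (raw camera digital numbers), `"fW"`
#'   (calibrated light power) or `"dff"` (baseline-normalized change).
#' @param roi_id Identifier of the ROI the trace was extracted from.
#'
#' @return A tibble of class `fluor_trace` with columns `time` and `value`.
#' @export
#' @examples
#' tr <- fluor_trace(rnorm(300, 1000, 5), frame_rate = 30)
#' frame_rate(tr)
fluor_trace <- function(values, frame_rate, unit = "counts", roi_id = "roi1") {
  stopifnot(is.numeric(values), length(values) > 0)
  if (!all(is.finite(values))) {
    rlang::abort("fluorescence values must be finite")
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0) {
    rlang::abort("`frame_rate` must be a single positive number")
  }
  unit <- match.arg(unit, c("counts", "fW", "dff"))
  out <- tibble::tibble(
    time = (seq_along(values) - 1) / frame_rate,
    value = as.numeric(values)
  )
  attr(out, "frame_rate") <- frame_rate
  attr(out, "unit") <- unit
  attr(out, "roi_id") <- roi_id
  class(out) <- c("fluor_trace", class(out))
  out
}

#' Membrane-voltage trace container
#'
#' @param values Numeric vector of membrane potential samples in mV.
#' @param sampling_rate Sampling rate in Hz (at least 1000).
#' @param cell_id Identifier of the recorded cell.
#'
#' @return A tibble of class `vm_trace` with columns `time` (s) and `vm` (mV).
#' @export
vm_trace <- function(values, sampling_rate, cell_id = "cell1") {
  stopifnot(is.numeric(values), length(values) > 0)
  if (!all(is.finite(values))) rlang::abort("voltage values must be finite")
  if (!is.numeric(sampling_rate) || sampling_rate < 1000) {
    rlang::abort("`sampling_rate` must be >= 1000 Hz")
  }
  out <- tibble::tibble(
    time = (seq_along(values) - 1) / sampling_rate,
    vm = as.numeric(values)
  )
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "cell_id") <- cell_id
  class(out) <- c("vm_trace", class(out))
  out
}

#' @rdname fluor_trace
#' @param trace A `fluor_trace` or `vm_trace`.
#' @export
frame_rate <- function(trace) {
  fr <- attr(trace, "frame_rate") %||% attr(trace, "sampling_rate")
  if (is.null(fr)) rlang::abort("trace carries no frame/sampling rate")
  fr
}

#' @rdname fluor_trace
#' @export
trace_unit <- function(trace) attr(trace, "unit") %||% "mV"

#' @rdname fluor_trace
#' @export
roi_id <- function(trace) attr(trace, "roi_id") %||% attr(trace, "cell_id")

trace_values <- function(trace) {
  if (inherits(trace, "vm_trace")) trace$vm else trace$value
}

# rebuild a trace with new values, keeping metadata
with_values <- function(trace, values, unit = NULL) {
  if (inherits(trace, "vm_trace")) {
    out <- vm_trace(values, frame_rate(trace), cell_id = roi_id(trace))
  } else {
    out <- fluor_trace(values, frame_rate(trace),
                       unit = unit %||% trace_unit(trace),
                       roi_id = roi_id(trace))
  }
  out
}

#' Read and write trace tables
#'
#' Plain-CSV interchange for traces: columns `time_s` and `value` (fluorescence,
#' with the unit recorded in a `unit` column) or `time_s` and `vm_mV` (voltage).
#'
#' @param path CSV file path.
#' @param trace Trace to write.
#' @return `read_trace_csv()` returns a `fluor_trace` or `vm_trace`;
#'   `write_trace_csv()` returns `path` invisibly.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  dt <- stats::median(diff(df$time_s))
  if ("vm_mV" %in% names(df)) {
    vm_trace(df$vm_mV, sampling_rate = 1 / dt)
  } else {
    unit <- if ("unit" %in% names(df)) as.character(df$unit[1]) else "counts"
    fluor_trace(df$value, frame_rate = 1 / dt, unit = unit)
  }
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  if (inherits(trace, "vm_trace")) {
    df <- data.frame(time_s = trace$time, vm_mV = trace$vm)
  } else {
    df <- data.frame(time_s = trace$time, value = trace$value,
                     unit = trace_unit(trace))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
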