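#' Camera sensor model
#'
#' Describes the linear scientific-CMOS sensor used to convert digital counts
#' to photon-derived light power. Defaults are the well-depth figures of the
#' imaging system used for IO recordings: 600,000 electrons full-well,
#' 130 electrons RMS dark noise, 16-bit digitization.
#'
#' @param full_well Full-well capacity in electrons.
#' @param dark_noise Dark (read) noise in electrons RMS.
#' @param digital_max Maximum digital number (counts) of the ADC.
#' @param electron_charge_energy Energy per electron in joules. Kept at the
#'   rounded 1.6e-19 J used for the published power scale.
#' @param frame_rate Optional acquisition frame rate in frames per second.
#'
#' @return A list of class `camera_model`.
#' @export
#' @examples
#' camera_model()
camera_model <- function(full_well = 600000, dark_noise = 130,
                         digital_max = 65535,
                         electron_charge_energy = 1.6e-19,
                         frame_rate = 30) {
  if (!(full_well > dark_noise && dark_noise > 0)) {
    rlang::abort("camera model requires full_well > dark_noise > 0")
  }
  if (digital_max <= 0) rlang::abort("digital_max must be positive")
  structure(
    list(full_well = full_well, dark_noise = dark_noise,
         digital_max = digital_max,
         electron_charge_energy = electron_charge_energy,
         frame_rate = frame_rate),
    class = "camera_model"
  )
}

#' Convert camera counts to light power
#'
#' Maps raw digital counts to calibrated light power in femtowatts,
#' assuming a linear sensor in which `digital_max` counts correspond to a
#' full well of electrons. Per frame,
#' electrons = counts x full_well / digital_max, and the equivalent continuous
#' power is electrons x 1.6e-19 J x frame_rate, reported in fW. The mapping is
#' strictly linear in counts and in frame rate, which makes recordings at
#' different frame rates comparable on one power scale.
#'
#' @param trace A `fluor_trace` in `"counts"` units.
#' @param camera A [camera_model()].
#'
#' @return A `fluor_trace` in `"fW"` units.
#' @export
#' @examples
#' tr <- fluor_trace(rep(65535, 10), frame_rate = 30)
#' counts_to_power(tr, camera_model())$value[1] # 2880 fW
counts_to_power <- function(trace, camera = camera_model()) {
  if (trace_unit(trace) != "counts") {
    rlang::abort("counts_to_power() expects a trace in 'counts' units")
  }
  v <- trace$value
  if (any(v > camera$digital_max)) {
    rlang::abort(sprintf(
      "saturated frames: %d counts value(s) exceed digital_max = %d",
      sum(v > camera$digital_max), camera$digital_max))
  }
  electrons <- v * camera$full_well / camera$digital_max
  power_w <- electrons * camera$electron_charge_energy * frame_rate(trace)
  with_values(trace, power_w * 1e15, unit = "fW")
}

#' @rdname counts_to_power
#' @details `power_to_counts()` is the exact inverse (before quantization) and
#'   is used by the fluorescence forward model.
#' @export
power_to_counts <- function(trace, camera = camera_model()) {
  if (trace_unit(trace) != "fW") {
    rlang::abort("power_to_counts() expects a trace in 'fW' units")
  }
  power_w <- trace$value * 1e-15
  electrons <- power_w / (camera$electron_charge_energy * frame_rate(trace))
  with_values(trace, electrons * camera$digital_max / camera$full_well,
              unit = "counts")
}

#' Extract an ROI-averaged trace from an image series
#'
#' The per-frame raw value of an ROI is the arithmetic mean of all pixels
#' inside it, matching the manual soma-ROI extraction workflow.
#'
#' @param image_series A 3-D numeric array `[row, col, frame]`.
#' @param roi Either a logical matrix of the same spatial size as one frame, or
#'   a data frame with integer pixel coordinates `row`, `col` (1-based).
#' @param frame_rate Frames per second of the series.
#' @param roi_id Identifier for the returned trace.
#'
#' @return A `fluor_trace` in `"counts"` units.
#' @export
extract_roi_trace <- function(image_series, roi, frame_rate = 30,
                              roi_id = "roi1") {
  stopifnot(is.array(image_series), length(dim(image_series)) == 3)
  d <- dim(image_series)
  if (is.matrix(roi) && is.logical(roi)) {
    if (!all(dim(roi) == d[1:2])) {
      rlang::abort("logical ROI mask must match frame dimensions")
    }
    idx <- which(roi)
  } else if (is.data.frame(roi)) {
    if (any(roi$row < 1 | roi$row > d[1] | roi$col < 1 | roi$col > d[2])) {
      rlang::abort("ROI pixel coordinates fall outside the image")
    }
    idx <- (roi$col - 1) * d[1] + roi$row
  } else {
    rlang::abort("`roi` must be a logical mask or a data frame of row/col")
  }
  if (length(idx) == 0) rlang::abort("empty ROI")
  npix <- d[1] * d[2]
  vals <- vapply(seq_len(d[3]), function(f) {
    mean(image_series[(f - 1) * npix + idx])
  }, numeric(1))
  fluor_trace(vals, frame_rate = frame_rate, unit = "counts", roi_id = roi_id)
}

#' Read a grayscale TIFF stack as an image series
#'
#' Loads a multi-frame TIFF into the `[row, col, frame]` array layout used by
#' [extract_roi_trace()]. Requires the `tiff` package.
#'
#' @param path TIFF file path.
#' @return A 3-D numeric array.
#' @export
read_image_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    rlang::abort("reading TIFF stacks requires the 'tiff' package")
  }
  frames <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (length(dim(frames[[1]])) != 2) {
    rlang::abort("only single-channel (grayscale) TIFF stacks are supported")
  }
  # integer TIFFs come back rescaled to [0, 1]; restore raw counts
  fmt <- attr(frames[[1]], "sample.format") %||% "uint"
  bits <- attr(frames[[1]], "bits.per.sample") %||% 16
  scale <- if (identical(fmt, "uint")) 2^bits - 1 else 1
  array(unlist(frames) * scale, dim = c(dim(frames[[1]]), length(frames)))
}

#' Baseline fluorescence before an event
#'
#' F0 ("Fzero-live") is the minimal value in the 500 ms window immediately
#' preceding the event onset. When the onset lies closer than the window to
#' the start of the trace, the minimum is taken over the available prefix.
#'
#' @param trace A `fluor_trace`.
#' @param onset 1-based frame index of the event onset.
#' @param window_ms Window length before onset, in ms.
#'
#' @return Scalar baseline in the trace's unit.
#' @export
baseline_f0 <- function(trace, onset, window_ms = 500) {
  if (onset < 1 || onset > nrow(trace)) rlang::abort("onset outside trace")
  nw <- max(1, round(window_ms / 1000 * frame_rate(trace)))
  lo <- max(1, onset - nw)
  if (onset == 1) rlang::abort("no samples precede the onset")
  min(trace$value[lo:(onset - 1)])
}

#' Baseline-normalized fluorescence change
#'
#' @param trace A `fluor_trace`.
#' @param f0 Positive baseline in the same unit as the trace.
#'
#' @return A `fluor_trace` in `"dff"` units, values `(F - f0) / f0`.
#' @export
dff <- function(trace, f0) {
  if (!is.numeric(f0) || length(f0) != 1 || f0 <= 0) {
    rlang::abort("`f0` must be a single positive number")
  }
  with_values(trace, (trace$value - f0) / f0, unit = "dff")
}
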