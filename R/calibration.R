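#' Fit the rise-time-to-spike-width calibration
#'
#' Ordinary least-squares line `width = slope * rise_time + intercept` relating
#' the GCaMP6s calcium-event rise time (ms) to the electrophysiological
#' calcium-shoulder spike width (ms) measured in paired recordings.
#'
#' @param rise_times Calcium-event rise times, ms.
#' @param widths Paired spike widths, ms.
#' @return An object of class `io_calibration` with `slope`, `intercept` and
#'   the underlying `lm` fit; supports [rt_to_width()], `tidy()`, `glance()`,
#'   `predict()` and `print()`.
#' @export
#' @examples
#' rt <- seq(200, 450, length.out = 20)
#' fit_calibration(rt, 0.06 * rt - 7.5)
fit_calibration <- function(rise_times, widths) {
  if (length(rise_times) != length(widths)) {
    rlang::abort("rise_times and widths must be paired")
  }
  if (length(rise_times) < 3) {
    rlang::abort("at least 3 paired observations are required")
  }
  if (stats::var(rise_times) == 0) {
    rlang::abort("rise times have zero variance; the slope is unidentifiable")
  }
  d <- data.frame(rt = rise_times, width = widths)
  fit <- stats::lm(width ~ rt, data = d)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         fit = fit, n = nrow(d),
         sigma = suppressWarnings(summary(fit))$sigma,
         r = stats::cor(d$rt, d$width)),
    class = "io_calibration"
  )
}

#' Default literature-anchored calibration
#'
#' The published relation: every 100 ms of calcium-event rise time adds about
#' 6 ms of spike width, and the shortest events (200 ms rise time) correspond
#' to 4-5 ms wide spikes. Taking the 4.5 ms midpoint of that range gives
#' `width = 0.06 * RT - 7.5` (ms).
#'
#' @param anchor_width_ms Width assigned to a 200 ms rise time (default the
#'   4.5 ms midpoint; configurable).
#' @return An `io_calibration` with slope 0.06 and intercept
#'   `anchor_width_ms - 12`.
#' @export
#' @examples
#' rt_to_width(351, default_calibration()) # ~13.6 ms, the in-vivo mean width
default_calibration <- function(anchor_width_ms = 4.5) {
  structure(
    list(slope = 0.06, intercept = anchor_width_ms - 0.06 * 200,
         fit = NULL, n = NA_integer_, sigma = NA_real_, r = NA_real_),
    class = "io_calibration"
  )
}

#' @export
print.io_calibration <- function(x, ...) {
  cat(sprintf("<io_calibration> width_ms = %.4f * RT_ms %+.4f", x$slope,
              x$intercept))
  if (!is.null(x$fit)) cat(sprintf("  (n = %d, r = %.3f)", x$n, x$r))
  cat("\n")
  invisible(x)
}

#' Predict spike width from calcium-event rise time
#'
#' Applies the linear calibration, flooring at 0 ms. Rise times shorter than
#' 150 ms fall outside the domain where calcium events correspond to normal
#' IO spikes (they mark "short IO spikes", sIO-s) and trigger a warning.
#'
#' @param rt Rise times in ms (non-negative).
#' @param model An `io_calibration`.
#' @return Predicted widths in ms.
#' @export
rt_to_width <- function(rt, model = default_calibration()) {
  if (any(rt < 0)) rlang::abort("rise times must be non-negative")
  if (any(rt < 150)) {
    rlang::warn(sprintf(
      "%d rise time(s) below 150 ms: outside the normal-IO-spike domain (sIO-s); prediction unreliable",
      sum(rt < 150)))
  }
  pmax(model$slope * rt + model$intercept, 0)
}

#' @export
predict.io_calibration <- function(object, newdata, ...) {
  rt_to_width(newdata, object)
}

#' Expected spikelet count of an axonal burst
#'
#' IO axons translate the somatic calcium shoulder into a high-frequency
#' burst. Assuming 270 Hz burst firing, a spike of width w ms carries the
#' initial spike plus one spikelet per full inter-spikelet interval:
#' `1 + floor(w * f / 1000)`. The counting rule is exposed as an argument
#' because the informal published expectation does not pin a unique
#' floor/round convention.
#'
#' @param width_ms Spike width(s), ms (non-negative).
#' @param burst_freq Burst frequency in Hz.
#' @param rule Function of `(width_ms, burst_freq)` returning the count.
#' @return Integer spikelet counts.
#' @export
#' @examples
#' expected_spikelet_count(13.7) # 4
expected_spikelet_count <- function(width_ms, burst_freq = 270,
                                    rule = function(w, f) 1 + floor(w * f / 1000)) {
  if (any(width_ms < 0)) rlang::abort("width must be non-negative")
  as.integer(rule(width_ms, burst_freq))
}

#' Tidy and summarize a calibration fit
#'
#' @param x An `io_calibration`.
#' @param ... Unused.
#' @return `tidy()` gives one row per model term; `glance()` a one-row model
#'   summary (`r.squared`, `sigma`, `nobs`, `slope`, `intercept`).
#' @importFrom generics tidy
#' @method tidy io_calibration
#' @export
tidy.io_calibration <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = c("(Intercept)", "rt"),
                          estimate = c(x$intercept, x$slope),
                          std.error = NA_real_, statistic = NA_real_,
                          p.value = NA_real_))
  }
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = rownames(s), estimate = unname(s[, 1]),
                 std.error = unname(s[, 2]), statistic = unname(s[, 3]),
                 p.value = unname(s[, 4]))
}

#' @rdname tidy.io_calibration
#' @importFrom generics glance
#' @method glance io_calibration
#' @export
glance.io_calibration <- function(x, ...) {
  tibble::tibble(
    r.squared = if (is.null(x$fit)) NA_real_ else
      suppressWarnings(summary(x$fit))$r.squared,
    sigma = x$sigma, nobs = x$n, slope = x$slope, intercept = x$intercept)
}
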