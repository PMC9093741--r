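#' Calcium-event detection parameters
#'
#' Events (eCas) are detected from the maximal instantaneous slope increase of
#' the fluorescence trace, with a robust z-threshold of 4 and a minimal 500 ms
#' peak-to-peak separation. Because the instantaneous first difference at
#' video rate is dominated by photon shot noise, the slope is computed on a
#' short centered moving average of the trace; `smooth_ms` sets its width and
#' the onset estimate is compensated for the smoother's spread.
#'
#' @param z_threshold Slope z-score threshold (robust, MAD-based).
#' @param min_separation_ms Minimal peak-to-peak separation; closer events are
#'   merged keeping the larger peak (ties keep the earlier one).
#' @param pre_ms,post_ms Alignment window before/after onset used for
#'   baselines, peak search and waveform alignment.
#' @param smooth_ms Width of the centered moving-average pre-smoother used by
#'   slope-based detection.
#' @param peak_smooth_ms Wider smoother used only for locating the transient
#'   peak in [event_metrics()]; more averaging costs a small fixed lag but
#'   suppresses correlated shot-noise bumps on the flat transient top.
#'
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(z_threshold = 4, min_separation_ms = 500,
                             pre_ms = 500, post_ms = 3000, smooth_ms = 150,
                             peak_smooth_ms = 200) {
  stopifnot(z_threshold > 0, min_separation_ms > 0)
  structure(list(z_threshold = z_threshold,
                 min_separation_ms = min_separation_ms,
                 pre_ms = pre_ms, post_ms = post_ms, smooth_ms = smooth_ms,
                 peak_smooth_ms = peak_smooth_ms),
            class = "detection_params")
}

# centered moving average with edge replication; k forced odd
smooth_trace_values <- function(v, fr, smooth_ms) {
  k <- max(1L, 2L * round(smooth_ms * fr / 2000) + 1L)
  if (k == 1L || k >= length(v)) return(list(values = v, k = 1L))
  h <- (k - 1L) %/% 2L
  padded <- c(rep(v[1], h), v, rep(v[length(v)], h))
  sm <- stats::filter(padded, rep(1 / k, k), sides = 2)
  list(values = as.numeric(sm[(h + 1):(h + length(v))]), k = k)
}

# sub-frame peak time as the centroid of the near-maximum plateau: the set of
# samples within one noise SD of the segment maximum, with both plateau edges
# located by linear interpolation. Robust to the flat, asymmetric top of
# GCaMP6s transients, where a plain argmax is dragged by shot noise; exact on
# noise-free waveforms (the plateau collapses to the true peak).
peak_centroid <- function(vs, seg, noise_sd) {
  m <- max(vs[seg])
  lev <- m - noise_sd
  above <- which(vs[seg] >= lev)
  i1 <- above[1]
  i2 <- max(above)
  left <- if (i1 == 1) seg[1] else {
    a <- vs[seg[i1 - 1]]
    seg[i1 - 1] + (lev - a) / (vs[seg[i1]] - a)
  }
  right <- if (i2 == length(seg)) seg[length(seg)] else {
    b <- vs[seg[i2 + 1]]
    seg[i2] + (vs[seg[i2]] - lev) / (vs[seg[i2]] - b)
  }
  (left + right) / 2
}

#' Detect calcium events in a fluorescence trace
#'
#' Candidate onsets are frames where the z-score of the instantaneous slope
#' (first difference of the lightly smoothed trace, z-scored against the
#' robust 1.4826 x MAD spread of the whole-trace slope) reaches the
#' threshold. Each onset is refined to the last preceding sample with
#' non-positive slope (corrected for the smoother's group delay); the peak is
#' the local maximum before the slope stays negative for at least 3 frames.
#' Events whose peaks fall closer than the minimal separation are merged,
#' keeping the larger peak. Events with a second supra-threshold onset inside
#' their rising segment are flagged `"double"` (the automated surrogate for
#' manual curation of stacked events); all events are returned with a `flag`
#' column so a review table can be written.
#'
#' @param trace A `fluor_trace` of at least 2 s.
#' @param params A [detection_params()].
#'
#' @return A tibble with one row per event: `roi_id`, `onset_frame`,
#'   `peak_frame` (1-based), `onset_s`, `peak_s`, `peak_value`, `flag`.
#'   A zero-variance trace yields zero rows.
#' @export
detect_events <- function(trace, params = detection_params()) {
  fr <- frame_rate(trace)
  v <- trace$value
  n <- length(v)
  if (n / fr < 2) rlang::abort("trace must be at least 2 s long")
  empty <- tibble::tibble(roi_id = character(0), onset_frame = integer(0),
                          peak_frame = integer(0), onset_s = numeric(0),
                          peak_s = numeric(0), peak_value = numeric(0),
                          flag = character(0))
  sm <- smooth_trace_values(v, fr, params$smooth_ms)
  vs <- sm$values
  shift <- (sm$k - 1L) %/% 2L
  slope <- diff(vs)
  sd_r <- stats::mad(slope)
  if (sd_r == 0) return(empty)
  z <- (slope - stats::median(slope)) / sd_r
  cand <- which(z >= params$z_threshold)
  if (!length(cand)) return(empty)
  runs <- split(cand, cumsum(c(1, diff(cand) > 1)))
  run_starts <- vapply(runs, `[`, integer(1), 1)

  # walk-back stop level: "non-positive" slope up to the robust noise spread,
  # so correlated noise runs in the smoothed slope cannot drag the onset early
  q <- stats::median(slope) + sd_r
  ev <- purrr::map(runs, function(run) {
    i0 <- run[1]
    j <- i0
    while (j > 1 && slope[j - 1] > q) j <- j - 1
    onset <- min(n, j + shift)
    # forward scan: stop when slope stays negative >= 3 frames
    stop_at <- n
    m <- i0
    while (m <= length(slope) - 2) {
      if (all(slope[m:(m + 2)] < 0)) { stop_at <- min(n, m + shift); break }
      m <- m + 1
    }
    seg <- onset:max(onset, stop_at)
    peak <- seg[which.max(vs[seg])]
    # stacked event: a later candidate run starting within the rise segment
    dbl <- any(run_starts + shift > onset + 1 & run_starts + shift < peak &
               !(run_starts %in% run))
    tibble::tibble(onset_frame = as.integer(onset),
                   peak_frame = as.integer(peak),
                   peak_value = vs[peak],
                   flag = if (dbl) "double" else "ok")
  })
  ev <- dplyr::distinct(dplyr::bind_rows(ev), .data$peak_frame,
                        .keep_all = TRUE)
  ev <- dplyr::arrange(ev, .data$onset_frame)
  ev <- merge_close_peaks(ev, min_gap = params$min_separation_ms / 1000 * fr)
  tibble::tibble(
    roi_id = roi_id(trace),
    onset_frame = ev$onset_frame, peak_frame = ev$peak_frame,
    onset_s = (ev$onset_frame - 1) / fr, peak_s = (ev$peak_frame - 1) / fr,
    peak_value = ev$peak_value, flag = ev$flag
  )
}

# iteratively merge events whose peaks are closer than min_gap frames,
# keeping the larger peak (tie -> earlier)
merge_close_peaks <- function(ev, min_gap) {
  repeat {
    if (nrow(ev) < 2) return(ev)
    gaps <- diff(ev$peak_frame)
    i <- which(gaps < min_gap)[1]
    if (is.na(i)) return(ev)
    drop <- if (ev$peak_value[i + 1] > ev$peak_value[i]) i else i + 1
    ev <- ev[-drop, ]
  }
}

#' Complete event waveform metrics
#'
#' For each detected event: the baseline `f0` is the minimum of the 500 ms
#' window before onset ([baseline_f0()]); `f_peak` is the maximal fluorescence
#' within the post-onset alignment window (truncated at the next event's onset
#' or the end of the trace, in which case the event is flagged truncated);
#' the rise time is the onset-to-peak interval; `dff_peak = (f_peak - f0)/f0`.
#' The peak time is located at sub-frame resolution as the centroid of the
#' near-maximum plateau of the lightly smoothed trace (all samples within one
#' noise SD of the maximum), so rise times are neither quantized to whole
#' frames nor dragged along the slow decay by the shot-noise argmax; the peak
#' intensity is read from the raw trace at the peak frame.
#'
#' @param trace The `fluor_trace` the events were detected in (fW or counts).
#' @param events Tibble from [detect_events()].
#' @param params The [detection_params()] used at detection.
#'
#' @return The events tibble with columns `f0`, `f_peak`, `rise_time_ms`,
#'   `dff_peak` and `truncated` added, `peak_frame`/`peak_s` updated.
#' @export
event_metrics <- function(trace, events, params = detection_params()) {
  fr <- frame_rate(trace)
  n <- nrow(trace)
  if (nrow(events) == 0) {
    return(dplyr::mutate(events, f0 = numeric(0), f_peak = numeric(0),
                         rise_time_ms = numeric(0), dff_peak = numeric(0),
                         truncated = logical(0)))
  }
  if (any(events$onset_frame < 1 | events$onset_frame > n)) {
    rlang::abort("event onsets fall outside the trace")
  }
  sm <- smooth_trace_values(trace$value, fr,
                            params$peak_smooth_ms %||% params$smooth_ms)
  vs <- sm$values
  # noise SD of the smoothed trace, from the robust whole-trace slope spread
  noise_sd <- stats::mad(diff(vs)) * sqrt(sm$k / 2)
  margin <- (sm$k - 1L) %/% 2L + 4L
  post <- round(params$post_ms / 1000 * fr)
  next_onset <- c(events$onset_frame[-1] - 1L, n)
  out <- purrr::map(seq_len(nrow(events)), function(i) {
    on <- events$onset_frame[i]
    hi <- min(on + post, next_onset[i], n)
    truncated <- (on + post) > n
    # bound the rise-time peak search by the detection-stage peak (where the
    # slope first stays negative), so the slow noisy decay cannot pull the
    # argmax hundreds of ms past the true transient peak
    hi_rise <- if (!is.null(events$peak_frame) &&
                   !is.na(events$peak_frame[i]) &&
                   events$peak_frame[i] >= on) {
      min(hi, events$peak_frame[i] + margin)
    } else hi
    seg <- on:hi_rise
    pk <- seg[which.max(vs[seg])]
    pk_frac <- peak_centroid(vs, seg, 1.5 * noise_sd)
    f0 <- baseline_f0(trace, on, window_ms = params$pre_ms)
    # peak *position* from the smoothed trace, peak *intensity* from the raw
    # trace at that frame: unbiased in noise, exact on clean waveforms
    f_peak <- trace$value[pk]
    tibble::tibble(peak_frame = as.integer(pk), f0 = f0, f_peak = f_peak,
                   rise_time_ms = (pk_frac - on) / fr * 1000,
                   dff_peak = (f_peak - f0) / f0,
                   truncated = truncated)
  })
  out <- dplyr::bind_rows(out)
  dplyr::mutate(events,
                peak_frame = out$peak_frame,
                peak_s = (out$peak_frame - 1) / fr,
                peak_value = out$f_peak,
                f0 = out$f0, f_peak = out$f_peak,
                rise_time_ms = out$rise_time_ms, dff_peak = out$dff_peak,
                truncated = out$truncated)
}

#' Align event waveforms on their onsets
#'
#' Cuts onset-aligned segments (`pre_ms` before to `post_ms` after onset) into
#' a matrix, one row per event. Rows whose window exceeds the trace bounds are
#' padded with `NA` and excluded from averaging (see the `complete` attribute).
#'
#' @param trace A `fluor_trace`.
#' @param events Tibble from [detect_events()].
#' @param pre_ms,post_ms Window around onset in ms.
#'
#' @return A numeric matrix (events x samples) with attributes `complete`
#'   (logical per row) and `time_ms` (per column, 0 = onset). Zero events give
#'   a 0-row matrix.
#' @export
align_events <- function(trace, events, pre_ms = 500, post_ms = 3000) {
  fr <- frame_rate(trace)
  npre <- round(pre_ms / 1000 * fr)
  npost <- round(post_ms / 1000 * fr)
  width <- npre + npost + 1
  time_ms <- (seq_len(width) - npre - 1) / fr * 1000
  m <- matrix(NA_real_, nrow(events), width)
  complete <- logical(nrow(events))
  v <- trace$value
  for (i in seq_len(nrow(events))) {
    idx <- (events$onset_frame[i] - npre):(events$onset_frame[i] + npost)
    ok <- idx >= 1 & idx <= length(v)
    m[i, ok] <- v[idx[ok]]
    complete[i] <- all(ok)
  }
  attr(m, "complete") <- complete
  attr(m, "time_ms") <- time_ms
  m
}

#' @rdname align_events
#' @param aligned Matrix from `align_events()`.
#' @return `average_aligned()` returns the column mean over complete rows.
#' @export
average_aligned <- function(aligned) {
  keep <- attr(aligned, "complete")
  if (!any(keep)) rlang::abort("no complete rows to average")
  colMeans(aligned[keep, , drop = FALSE])
}
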