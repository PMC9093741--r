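#' Subthreshold-oscillation analysis parameters
#'
#' @param band Analysis band in Hz; IO STOs live in 3-12 Hz.
#' @param segment_s Welch segment length in seconds (0.5 Hz resolution on the
#'   10 s acquisitions used throughout).
#' @param overlap Welch segment overlap fraction.
#' @param dff_threshold_pct Fluorescence oscillation threshold: band-limited
#'   STO amplitude in % DFF above which a cell counts as oscillating
#'   (0.12 %, the 5th percentile of electrophysiologically confirmed
#'   oscillators).
#' @param vm_threshold Voltage oscillation threshold: 3-12 Hz band power in
#'   mV^2 above which a cell counts as oscillating (1 mV^2 RMS).
#'
#' @return A list of class `sto_params`.
#' @export
sto_params <- function(band = c(3, 12), segment_s = 2, overlap = 0.5,
                       dff_threshold_pct = 0.12, vm_threshold = 1) {
  stopifnot(band[1] < band[2], dff_threshold_pct > 0, vm_threshold > 0)
  structure(list(band = band, segment_s = segment_s, overlap = overlap,
                 dff_threshold_pct = dff_threshold_pct,
                 vm_threshold = vm_threshold),
            class = "sto_params")
}

#' Excise calcium-event windows from a trace
#'
#' IO spike transients leak power into the 0-3 Hz band and, through their
#' decaying flanks, can contaminate the STO band. Each event window (100 ms
#' before onset to `post_s` after, roughly three GCaMP6s decay constants) is
#' replaced by linear interpolation between the window endpoints so the STO
#' spectrum is estimated on spike-free signal of unchanged length.
#'
#' @param trace A `fluor_trace`.
#' @param events Tibble from [detect_events()].
#' @param pre_ms Excision start before onset, ms.
#' @param post_s Excision end after onset, seconds.
#'
#' @return The trace with event windows interpolated.
#' @export
excise_events <- function(trace, events, pre_ms = 100, post_s = 4) {
  if (nrow(events) == 0) return(trace)
  fr <- frame_rate(trace)
  n <- nrow(trace)
  v <- trace$value
  cut <- logical(n)
  for (i in seq_len(nrow(events))) {
    lo <- max(1, events$onset_frame[i] - round(pre_ms / 1000 * fr))
    hi <- min(n, events$onset_frame[i] + round(post_s * fr))
    cut[lo:hi] <- TRUE
  }
  if (mean(cut) > 0.8) {
    rlang::abort("event windows cover more than 80% of the trace")
  }
  keep <- which(!cut)
  v[cut] <- stats::approx(keep, v[keep], xout = which(cut), rule = 2)$y
  with_values(trace, v)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward 3rd-order Butterworth band-pass; zero phase so oscillation
#' timing is preserved, DC removed by construction.
#'
#' @param trace A `fluor_trace` or `vm_trace`.
#' @param band Pass band in Hz.
#' @return The filtered trace.
#' @export
bandpass_trace <- function(trace, band = c(3, 12)) {
  fs <- frame_rate(trace)
  if (fs <= 2 * band[2]) {
    rlang::abort(sprintf(
      "sampling rate %.1f Hz cannot resolve a %.1f Hz band edge (Nyquist %.1f Hz)",
      fs, band[2], fs / 2))
  }
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  v <- trace_values(trace)
  with_values(trace, as.numeric(signal::filtfilt(bf, v - mean(v))))
}

# Blackman-windowed Welch periodogram, one-sided density scaling
welch_spectrum <- function(x, fs, segment_s = 2, overlap = 0.5) {
  nseg <- round(segment_s * fs)
  if (length(x) < nseg) rlang::abort("trace shorter than one Welch segment")
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- signal::blackman(nseg)
  u <- sum(w^2)
  nfreq <- floor(nseg / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (fs * u)
    p1 <- p[seq_len(nfreq)]
    last_double <- if (nseg %% 2 == 0) nfreq - 1 else nfreq
    p1[2:last_double] <- 2 * p1[2:last_double]
    acc <- acc + p1
  }
  tibble::tibble(freq = (seq_len(nfreq) - 1) * fs / nseg,
                 psd = acc / length(starts))
}

#' Welch power spectral density and STO band summary
#'
#' Averages Blackman-windowed periodograms (Welch, density scaling) and
#' summarizes the STO band: `peak_freq` is the frequency of maximal density in
#' the band, `band_power` the PSD integral over the band (for a sinusoid of
#' amplitude A inside the band this is A^2/2), and `amplitude` a
#' noise-floor-corrected estimate of the band-limited oscillation amplitude:
#' power is summed over the spectral main lobe around the peak (+/- 1.5 Hz),
#' the median in-band density outside that window is subtracted as the
#' shot-noise floor, and the result converted via `A = sqrt(2 P)`. For DFF
#' traces the amplitude is also reported in % as `dff_amp_pct`.
#'
#' @param trace A `fluor_trace` or `vm_trace` (or numeric vector with `fs`).
#' @param params An [sto_params()].
#' @param fs Sampling rate, only when `trace` is a bare numeric vector.
#'
#' @return An object of class `sto_result`: list with `spectrum` (tibble
#'   `freq`, `psd`), `peak_freq`, `band_power`, `amplitude`, `dff_amp_pct`
#'   (NA unless the input is in DFF units), `band`, `unit`, `n_segments`.
#' @export
welch_psd <- function(trace, params = sto_params(), fs = NULL) {
  if (is.numeric(trace) && is.null(dim(trace))) {
    stopifnot(!is.null(fs))
    x <- trace; unit <- "a.u."
  } else {
    x <- trace_values(trace); fs <- frame_rate(trace)
    unit <- if (inherits(trace, "vm_trace")) "mV" else trace_unit(trace)
  }
  spec <- welch_spectrum(x, fs, params$segment_s, params$overlap)
  df <- spec$freq[2] - spec$freq[1]
  in_band <- spec$freq >= params$band[1] & spec$freq <= params$band[2]
  if (!any(in_band)) rlang::abort("no spectral bins inside the band")
  band_power <- sum(spec$psd[in_band]) * df
  pk_i <- which(in_band)[which.max(spec$psd[in_band])]
  peak_freq <- spec$freq[pk_i]
  lobe <- in_band & abs(spec$freq - peak_freq) <= 1.5
  floor_psd <- if (sum(in_band & !lobe) >= 3) {
    stats::median(spec$psd[in_band & !lobe])
  } else 0
  peak_power <- sum(pmax(spec$psd[lobe] - floor_psd, 0)) * df
  amplitude <- sqrt(2 * max(peak_power, 0))
  n_segments <- length(seq(1, length(x) - round(params$segment_s * fs) + 1,
                           by = max(1, round(params$segment_s * fs *
                                             (1 - params$overlap)))))
  structure(
    list(spectrum = spec, peak_freq = peak_freq, band_power = band_power,
         amplitude = amplitude,
         dff_amp_pct = if (unit == "dff") amplitude * 100 else NA_real_,
         band = params$band, unit = unit, n_segments = n_segments),
    class = "sto_result"
  )
}

#' @export
print.sto_result <- function(x, ...) {
  cat(sprintf(
    "<sto_result> band %.0f-%.0f Hz | peak %.2f Hz | band power %.4g %s^2 | amplitude %.4g %s\n",
    x$band[1], x$band[2], x$peak_freq, x$band_power, x$unit, x$amplitude,
    x$unit))
  invisible(x)
}

#' Classify a cell as oscillating or non-oscillating
#'
#' Voltage modality: 3-12 Hz band power above 1 mV^2 RMS. Fluorescence
#' modality: band-limited STO amplitude above 0.12 % DFF.
#'
#' @param result An `sto_result` from [welch_psd()].
#' @param params An [sto_params()] carrying the two thresholds.
#' @param modality `"vm"` or `"fluorescence"`.
#' @return Logical.
#' @export
classify_oscillating <- function(result, params = sto_params(),
                                 modality = c("vm", "fluorescence")) {
  modality <- match.arg(modality)
  if (modality == "vm") {
    result$band_power > params$vm_threshold
  } else {
    amp_pct <- if (!is.na(result$dff_amp_pct)) result$dff_amp_pct
               else result$amplitude * 100
    amp_pct > params$dff_threshold_pct
  }
}

#' Frequency ratio between paired voltage and fluorescence STOs
#'
#' For a cell classified oscillating in both modalities, the ratio of the
#' voltage STO peak frequency to the fluorescence STO peak frequency (flat at
#' 1 when GCaMP6s faithfully reports the electrical oscillation).
#'
#' @param vm_result,fluo_result `sto_result`s of the two modalities.
#' @param params An [sto_params()].
#' @return Numeric ratio.
#' @export
frequency_match <- function(vm_result, fluo_result, params = sto_params()) {
  if (!classify_oscillating(vm_result, params, "vm") ||
      !classify_oscillating(fluo_result, params, "fluorescence")) {
    rlang::abort("frequency ratio is undefined for non-oscillating cells")
  }
  vm_result$peak_freq / fluo_result$peak_freq
}
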