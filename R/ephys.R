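#' Detect spikes in a membrane-voltage trace
#'
#' Events are depolarizations exceeding the trace baseline (its median) by
#' 10 mV. Each event's initiation point is the last sample before the rising
#' phase crosses baseline + 2 mV, a definition robust to ongoing STOs.
#' Events initiating within the refractory window are merged.
#'
#' @param trace A [vm_trace()] of at least 100 ms.
#' @param threshold_mv Detection threshold above baseline, mV.
#' @param init_mv Rise-crossing level defining the initiation point, mV.
#' @param refractory_ms Merge window, ms.
#'
#' @return Tibble with `init_index` (1-based sample), `init_s`, `peak_mv`.
#'   Empty for a silent trace.
#' @export
detect_spikes_vm <- function(trace, threshold_mv = 10, init_mv = 2,
                             refractory_ms = 20) {
  fs <- frame_rate(trace)
  v <- trace$vm
  if (length(v) / fs < 0.1) rlang::abort("trace must be at least 100 ms")
  base <- stats::median(v)
  above <- v >= base + threshold_mv
  empty <- tibble::tibble(init_index = integer(0), init_s = numeric(0),
                          peak_mv = numeric(0))
  if (!any(above)) return(empty)
  idx <- which(above)
  runs <- split(idx, cumsum(c(1, diff(idx) > 1)))
  inits <- purrr::map_int(runs, function(run) {
    j <- run[1]
    while (j > 1 && v[j - 1] > base + init_mv) j <- j - 1
    as.integer(max(1, j - 1))
  })
  peaks <- purrr::map_dbl(runs, function(run) max(v[run]))
  o <- order(inits)
  inits <- inits[o]; peaks <- peaks[o]
  keep <- c(TRUE, diff(inits) > refractory_ms / 1000 * fs)
  tibble::tibble(init_index = inits[keep],
                 init_s = (inits[keep] - 1) / fs,
                 peak_mv = peaks[keep])
}

#' Measure the calcium-shoulder spike width
#'
#' The IO spike width is the duration for which the waveform stays at least
#' 10 mV above the pre-spike baseline, from the first up-crossing to the first
#' down-crossing, with sub-sample linear interpolation at both crossings. The
#' threshold is relative to baseline, so the width is invariant to vertical
#' offsets. Waveforms that never reach the threshold (gap-junction spikelets)
#' return a width of 0 with `is_spikelet = TRUE`.
#'
#' @param waveform Numeric mV samples aligned at the initiation point, or a
#'   `vm_trace` segment.
#' @param baseline Pre-spike baseline in mV.
#' @param fs Sampling rate in Hz (taken from the trace if one is supplied).
#' @param threshold_mv Width threshold above baseline, mV.
#'
#' @return One-row tibble with `width_ms` and `is_spikelet`.
#' @export
spike_width <- function(waveform, baseline, fs = NULL, threshold_mv = 10) {
  if (inherits(waveform, "vm_trace")) {
    fs <- frame_rate(waveform)
    waveform <- waveform$vm
  }
  stopifnot(!is.null(fs))
  thr <- baseline + threshold_mv
  above <- waveform >= thr
  if (!any(above)) {
    return(tibble::tibble(width_ms = 0, is_spikelet = TRUE))
  }
  i_up <- which(above)[1]
  t_up <- if (i_up == 1) i_up else {
    i_up - 1 + (thr - waveform[i_up - 1]) / (waveform[i_up] - waveform[i_up - 1])
  }
  after <- which(!above & seq_along(waveform) > i_up)
  if (length(after) == 0) {
    t_dn <- length(waveform)
  } else {
    i_dn <- after[1]
    t_dn <- i_dn - 1 +
      (thr - waveform[i_dn - 1]) / (waveform[i_dn] - waveform[i_dn - 1])
  }
  tibble::tibble(width_ms = (t_dn - t_up) / fs * 1000, is_spikelet = FALSE)
}

#' Align spike waveforms on their initiation points
#'
#' @param trace A [vm_trace()].
#' @param spikes Tibble from [detect_spikes_vm()].
#' @param pre_ms,post_ms Window around initiation, ms.
#' @return Matrix (spikes x samples) with `time_ms` attribute; rows whose
#'   window leaves the trace are dropped.
#' @export
align_spikes <- function(trace, spikes, pre_ms = 5, post_ms = 50) {
  fs <- frame_rate(trace)
  npre <- round(pre_ms / 1000 * fs)
  npost <- round(post_ms / 1000 * fs)
  v <- trace$vm
  ok <- spikes$init_index - npre >= 1 & spikes$init_index + npost <= length(v)
  m <- t(vapply(spikes$init_index[ok], function(i) v[(i - npre):(i + npost)],
                numeric(npre + npost + 1)))
  attr(m, "time_ms") <- ((-npre):npost) / fs * 1000
  m
}

#' PCA of aligned spike waveforms
#'
#' Mean-centered (not scaled) principal-component analysis of the raw aligned
#' voltage waveforms. Explained-variance fractions sum to 1; the scores of
#' the first two components are the coordinates used for spike typing.
#'
#' @param waveforms Matrix (spikes x samples), at least 3 rows.
#' @return List of class `spike_pca`: `scores` (tibble `PC1`, `PC2`),
#'   `explained` (variance fractions), `components` (loadings), `prcomp`.
#' @export
pca_waveforms <- function(waveforms) {
  if (!is.matrix(waveforms) || nrow(waveforms) < 3) {
    rlang::abort("at least 3 waveforms are required for PCA")
  }
  if (sum(apply(waveforms, 2, stats::var)) == 0) {
    rlang::abort("degenerate input: identical waveforms have zero variance")
  }
  p <- stats::prcomp(waveforms, center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(scores = tibble::tibble(PC1 = p$x[, 1], PC2 = p$x[, 2]),
         explained = expl, components = p$rotation, prcomp = p),
    class = "spike_pca"
  )
}

#' Cluster spike waveforms by k-means with elbow selection
#'
#' Runs k-means (10 restarts, fixed seed) on the first two principal-component
#' scores for k = 1..`k_max` and selects k at the elbow of the within-cluster
#' sum-of-squares curve: the k of maximal perpendicular distance to the chord
#' joining the k = 1 and k = `k_max` points of the (normalized) curve.
#' Deterministic under a fixed seed; identical points collapse to k = 1.
#'
#' @param scores Tibble or matrix of PC scores (first two columns used).
#' @param k_max Maximal number of clusters tried.
#' @param seed Integer seed.
#' @return List of class `spike_clusters`: `labels` (integer vector), `k`,
#'   `wss` (curve over k), `centers`.
#' @export
cluster_spikes <- function(scores, k_max = 10, seed = 0L) {
  x <- as.matrix(as.data.frame(scores)[, 1:2])
  n_distinct <- nrow(unique(x))
  if (n_distinct == 1) {
    return(structure(list(labels = rep(1L, nrow(x)), k = 1L,
                          wss = 0, centers = x[1, , drop = FALSE]),
                     class = "spike_clusters"))
  }
  if (nrow(x) < k_max + 1) {
    rlang::abort("need at least k_max + 1 points for elbow selection")
  }
  k_max <- min(k_max, n_distinct)
  set.seed(seed)
  fits <- purrr::map(seq_len(k_max), function(k) {
    if (k == 1) {
      list(cluster = rep(1L, nrow(x)),
           tot.withinss = sum(scale(x, scale = FALSE)^2),
           centers = matrix(colMeans(x), 1))
    } else {
      stats::kmeans(x, centers = k, nstart = 10, iter.max = 100)
    }
  })
  wss <- purrr::map_dbl(fits, "tot.withinss")
  k <- elbow_k(wss)
  structure(list(labels = as.integer(fits[[k]]$cluster), k = k,
                 wss = wss, centers = fits[[k]]$centers),
            class = "spike_clusters")
}

# elbow of a decreasing curve: max perpendicular distance to the chord
# between the first and last points, on axis-normalized coordinates
elbow_k <- function(wss) {
  k_max <- length(wss)
  if (k_max <= 2) return(k_max)
  kx <- (seq_len(k_max) - 1) / (k_max - 1)
  rng <- max(wss) - min(wss)
  wy <- if (rng > 0) (wss - min(wss)) / rng else rep(0, k_max)
  # chord from (0, wy[1]) to (1, wy[k_max])
  dx <- 1; dy <- wy[k_max] - wy[1]
  d <- abs(dy * kx - dx * (wy - wy[1])) / sqrt(dx^2 + dy^2)
  which.max(d)
}

#' STO band power of a voltage trace
#'
#' Convenience wrapper delegating to [welch_psd()] with the voltage modality:
#' returns the 3-12 Hz band power in mV^2 (for a sinusoid of amplitude A,
#' A^2/2).
#'
#' @param trace A [vm_trace()].
#' @param params An [sto_params()].
#' @return Scalar band power, mV^2.
#' @export
sto_power_vm <- function(trace, params = sto_params()) {
  if (stats::var(trace$vm) == 0) return(0)
  welch_psd(trace, params)$band_power
}
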