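#' Simulation configuration for one IO cell
#'
#' Defines the phenomenological membrane-voltage and fluorescence model of a
#' single inferior-olive neuron: a sinusoidal subthreshold oscillation (STO,
#' physiological range 3.5-13 Hz), spikes consisting of a 1 ms sodium peak, a
#' calcium-shoulder plateau of configurable duration (up to ~20 ms or more in
#' real cells), and an after-hyperpolarization; small gap-junction spikelets;
#' and a GCaMP6s fluorescence channel with slow transients riding on an
#' expression-dependent baseline.
#'
#' @param duration Recording length in seconds.
#' @param fs_vm Voltage sampling rate, Hz.
#' @param fs_img Imaging frame rate, frames/s.
#' @param sto_freq STO frequency in Hz.
#' @param sto_amp STO amplitude in mV (half peak-to-peak).
#' @param baseline_vm Resting potential in mV.
#' @param spike_times Spike onset times in seconds.
#' @param shoulder_widths Calcium-shoulder durations in ms, one per spike,
#'   each in (0, 30].
#' @param spikelet_times Gap-junction spikelet times in seconds.
#' @param spikelet_amp Spikelet amplitude in mV.
#' @param f0 Baseline fluorescence power in fW (expression level).
#' @param sto_dff Peak DFF of the fluorescence STO component (dimensionless).
#' @param decay_tau GCaMP6s transient decay time constant in seconds.
#' @param dff_per_ms Peak transient DFF per ms of shoulder width
#'   (default 0.0035, i.e. 0.35 %/ms, placing a ~14 ms spike near 5 % DFF as
#'   seen in vivo).
#' @param vm_noise_sd Gaussian voltage noise SD in mV.
#' @param seed Integer seed; fixed seed gives bit-identical outputs.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 10, fs_vm = 10000, fs_img = 30,
                       sto_freq = 6, sto_amp = 0, baseline_vm = -55,
                       spike_times = numeric(0),
                       shoulder_widths = numeric(0),
                       spikelet_times = numeric(0), spikelet_amp = 2,
                       f0 = 400, sto_dff = 0, decay_tau = 1.5,
                       dff_per_ms = 0.0035,
                       vm_noise_sd = 0.2, seed = 1L) {
  if (duration <= 0) rlang::abort("duration must be positive")
  if (fs_vm < 20 * fs_img) rlang::abort("fs_vm must be at least 20 x fs_img")
  if (length(spike_times) != length(shoulder_widths)) {
    rlang::abort("one shoulder width per spike is required")
  }
  if (length(spike_times) &&
      (any(spike_times < 0) || any(spike_times >= duration))) {
    rlang::abort("spike_times must lie within [0, duration)")
  }
  if (length(shoulder_widths) &&
      (any(shoulder_widths <= 0) || any(shoulder_widths > 30))) {
    rlang::abort("shoulder_widths must lie in (0, 30] ms")
  }
  if (f0 < 0) rlang::abort("f0 must be non-negative")
  structure(
    list(duration = duration, fs_vm = fs_vm, fs_img = fs_img,
         sto_freq = sto_freq, sto_amp = sto_amp, baseline_vm = baseline_vm,
         spike_times = spike_times, shoulder_widths = shoulder_widths,
         spikelet_times = spikelet_times, spikelet_amp = spikelet_amp,
         f0 = f0, sto_dff = sto_dff, decay_tau = decay_tau,
         dff_per_ms = dff_per_ms, vm_noise_sd = vm_noise_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Expected calcium-event rise time for a spike width
#'
#' Inverse of the rise-time-to-width calibration: 6 ms of spike width per
#' 100 ms of rise time, anchored at 200 ms rise time for a 4.5 ms spike.
#'
#' @param width_ms Calcium-shoulder duration in ms.
#' @return Expected fluorescence rise time in ms.
#' @export
expected_rise_time <- function(width_ms) 200 + (width_ms - 4.5) * 100 / 6

#' Simulate an IO membrane-voltage trace
#'
#' Builds `baseline + STO sinusoid + spikes + spikelets + Gaussian noise`.
#' Each spike is a 1 ms triangular sodium peak reaching +80 mV over baseline,
#' followed by a +20 mV calcium-shoulder plateau of the configured width and a
#' -10 mV after-hyperpolarization decaying over ~50 ms. Spikelets are 10 ms
#' half-sine bumps. The trace is reproducible under a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A list with `trace` (a [vm_trace()]) and `truth`, the ground-truth
#'   manifest (spike times, shoulder widths, expected rise times, STO
#'   parameters and oscillating flag).
#' @export
simulate_vm <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  st <- config$spike_times
  sw <- config$shoulder_widths
  if (length(st) > 1) {
    o <- order(st)
    gaps_ms <- diff(st[o]) * 1000
    lim <- 1 + pmax(sw[o][-length(sw)], sw[o][-1])
    if (any(gaps_ms < lim)) {
      rlang::abort("overlapping spikes: spikes closer than their widths")
    }
  }
  n <- round(config$duration * config$fs_vm)
  t <- (seq_len(n) - 1) / config$fs_vm
  set.seed(config$seed)
  v <- config$baseline_vm +
    config$sto_amp * sin(2 * pi * config$sto_freq * t) +
    stats::rnorm(n, 0, config$vm_noise_sd)
  v <- v + vm_spike_component(t, st, sw, config$fs_vm)
  for (ts in config$spikelet_times) {
    rel <- t - ts
    in_b <- rel >= 0 & rel < 0.010
    v[in_b] <- v[in_b] + config$spikelet_amp * sin(pi * rel[in_b] / 0.010)
  }
  truth <- list(
    spike_times = st, shoulder_widths = sw,
    expected_rise_times = expected_rise_time(sw),
    spikelet_times = config$spikelet_times,
    sto_freq = config$sto_freq,
    oscillating = (config$sto_amp^2 / 2) > 1
  )
  list(trace = vm_trace(v, config$fs_vm), truth = truth)
}

# additive spike templates: sodium triangle (1 ms, +80 mV), shoulder plateau
# (+20 mV, width ms), AHP (-10 mV, tau 12.5 ms so ~50 ms total)
vm_spike_component <- function(t, spike_times, widths, fs) {
  out <- numeric(length(t))
  for (i in seq_along(spike_times)) {
    t0 <- spike_times[i]
    w <- widths[i] / 1000
    rel <- t - t0
    rise <- rel >= 0 & rel < 0.0005
    fall <- rel >= 0.0005 & rel < 0.001
    plat <- rel >= 0.001 & rel < 0.001 + w
    ahp <- rel >= 0.001 + w & rel < 0.001 + w + 0.050
    out[rise] <- out[rise] + 80 * rel[rise] / 0.0005
    out[fall] <- out[fall] + 80 - 60 * (rel[fall] - 0.0005) / 0.0005
    out[plat] <- out[plat] + 20
    out[ahp] <- out[ahp] - 10 * exp(-(rel[ahp] - 0.001 - w) / 0.0125)
  }
  out
}

#' Simulate a GCaMP6s fluorescence trace through the camera model
#'
#' Forward model: the ideal emitted power is
#' `P(t) = f0 * (1 + sto_dff * sin(2 pi f t) + sum of transients)`, each
#' transient an alpha-function rise peaking at its expected rise time (derived
#' from the spike's shoulder width) followed by a single-exponential decay,
#' with peak DFF proportional to the shoulder width. The power is converted to
#' expected electrons per frame (inverse of [counts_to_power()]), Poisson shot
#' noise is applied, Gaussian dark noise added, and the result quantized to
#' counts clipped at `digital_max`.
#'
#' @param config A [sim_config()]. `f0` must stay below 60 % of the power
#'   equivalent of the camera full well.
#' @param camera A [camera_model()].
#' @param noise If `FALSE`, shot/dark noise and quantization are disabled
#'   (counts remain fractional), for identity checks.
#' @return A list with `trace` (counts) and the ground-truth manifest.
#' @export
simulate_fluorescence <- function(config, camera = camera_model(),
                                  noise = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs_img
  full_well_fw <- camera$full_well * camera$electron_charge_energy * fs * 1e15
  if (config$f0 > 0.6 * full_well_fw) {
    rlang::abort(sprintf(
      "f0 = %.0f fW exceeds 60%% of the full-well-equivalent power (%.0f fW)",
      config$f0, 0.6 * full_well_fw))
  }
  n <- floor(config$duration * fs)
  t <- (seq_len(n) - 1) / fs
  rel_dff <- config$sto_dff * sin(2 * pi * config$sto_freq * t)
  for (i in seq_along(config$spike_times)) {
    rt <- expected_rise_time(config$shoulder_widths[i]) / 1000
    peak <- config$dff_per_ms * config$shoulder_widths[i]
    rel_dff <- rel_dff +
      peak * transient_shape(t - config$spike_times[i], rt, config$decay_tau)
  }
  power_fw <- config$f0 * (1 + rel_dff)
  electrons <- power_fw * 1e-15 / (camera$electron_charge_energy * fs)
  over <- which(electrons > camera$full_well)
  if (length(over)) {
    rlang::abort(sprintf(
      "simulated power exceeds the camera full well at %d frame(s): %s",
      length(over), paste(utils::head(over, 10), collapse = ", ")))
  }
  if (noise) {
    set.seed(config$seed + 1L)
    electrons <- stats::rpois(n, electrons) +
      stats::rnorm(n, 0, camera$dark_noise)
    counts <- round(electrons * camera$digital_max / camera$full_well)
    counts <- pmin(pmax(counts, 0), camera$digital_max)
  } else {
    counts <- electrons * camera$digital_max / camera$full_well
  }
  truth <- list(
    spike_times = config$spike_times,
    shoulder_widths = config$shoulder_widths,
    expected_rise_times = expected_rise_time(config$shoulder_widths),
    expected_dff_peaks = config$dff_per_ms * config$shoulder_widths,
    sto_freq = config$sto_freq, sto_dff = config$sto_dff, f0 = config$f0,
    oscillating = config$sto_dff * 100 > 0.12
  )
  list(trace = fluor_trace(counts, frame_rate = fs, unit = "counts"),
       truth = truth)
}

# unit-peak transient: alpha rise peaking at rt, exponential decay after
transient_shape <- function(rel_t, rt, decay_tau) {
  s <- numeric(length(rel_t))
  rise <- rel_t >= 0 & rel_t <= rt
  dec <- rel_t > rt
  s[rise] <- (rel_t[rise] / rt) * exp(1 - rel_t[rise] / rt)
  s[dec] <- exp(-(rel_t[dec] - rt) / decay_tau)
  s
}

#' Simulate a two-channel anatomy field with ground-truth somata
#'
#' Renders disk-shaped somata on an EGFP / tdTomato / NeuN image triplet.
#' Neuron soma areas are drawn from a truncated normal whose 5th percentile
#' lies above 100 um^2 and astrocyte areas from one whose 95th percentile lies
#' below it, mirroring the published percentile straddle (111 vs 96 um^2)
#' while guaranteeing exact separability at the 100 um^2 threshold. Neurons
#' receive cytosolic NeuN-channel intensity; astrocytes none. Per-cell
#' EGFP/tdTomato intensity ratio is configurable.
#'
#' @param n_neurons,n_astro Number of somata per class.
#' @param seed Integer seed.
#' @param img_size_px Image side length in pixels.
#' @param px_size_um Pixel size in um.
#' @param egfp_tdtomato_ratio Mean per-cell EGFP/tdTomato intensity ratio.
#' @param ratio_cv Lognormal coefficient of variation of the per-cell ratio.
#'
#' @return A list with `images` (matrices `egfp`, `tdtomato`, `neun`),
#'   `somata` (tibble: id, x/y centroid in um, area um^2, channel means,
#'   true class) and `px_size_um`.
#' @export
simulate_anatomy <- function(n_neurons, n_astro, seed = 1L,
                             img_size_px = 512, px_size_um = 1.22,
                             egfp_tdtomato_ratio = 1.2, ratio_cv = 0.05) {
  stopifnot(n_neurons >= 0, n_astro >= 0)
  set.seed(seed)
  n <- n_neurons + n_astro
  is_neuron <- rep(c(TRUE, FALSE), c(n_neurons, n_astro))
  areas <- c(rtrunc_norm(n_neurons, 145, 20, lower = 102),
             rtrunc_norm(n_astro, 68, 17, lower = 20, upper = 98))
  radii_px <- sqrt(areas / pi) / px_size_um
  # non-overlapping centroid placement by rejection
  cx <- cy <- numeric(n)
  margin <- max(radii_px, 0) + 2
  for (i in seq_len(n)) {
    for (try in 1:2000) {
      x <- stats::runif(1, margin, img_size_px - margin)
      y <- stats::runif(1, margin, img_size_px - margin)
      if (i == 1 || all(sqrt((x - cx[seq_len(i - 1)])^2 +
                             (y - cy[seq_len(i - 1)])^2) >
                        radii_px[i] + radii_px[seq_len(i - 1)] + 2)) break
      if (try == 2000) rlang::abort("could not place somata without overlap")
    }
    cx[i] <- x; cy[i] <- y
  }
  tdt <- pmax(stats::rnorm(n, 100, 10), 10)
  ratio <- egfp_tdtomato_ratio *
    stats::rlnorm(n, -log(1 + ratio_cv^2) / 2, sqrt(log(1 + ratio_cv^2)))
  egfp <- tdt * ratio
  neun_i <- ifelse(is_neuron, pmax(stats::rnorm(n, 120, 10), 50), 0)

  img_e <- img_t <- img_n <- matrix(0, img_size_px, img_size_px)
  for (i in seq_len(n)) {
    px <- disk_pixels(cx[i], cy[i], radii_px[i], img_size_px)
    img_e[px] <- egfp[i]
    img_t[px] <- tdt[i]
    img_n[px] <- neun_i[i]
  }
  somata <- tibble::tibble(
    id = seq_len(n),
    x_um = cx * px_size_um, y_um = cy * px_size_um,
    area_um2 = areas,
    egfp = egfp, tdtomato = tdt, neun = neun_i,
    true_class = ifelse(is_neuron, "neuron", "non-neuron")
  )
  list(images = list(egfp = img_e, tdtomato = img_t, neun = img_n),
       somata = somata, px_size_um = px_size_um)
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0) return(numeric(0))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out <= lower | out >= upper)
  }
  out
}

disk_pixels <- function(cx, cy, r, size) {
  xs <- max(1, floor(cx - r)):min(size, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(size, ceiling(cy + r))
  g <- expand.grid(row = ys, col = xs)
  keep <- (g$col - cx)^2 + (g$row - cy)^2 <= r^2
  (g$col[keep] - 1) * size + g$row[keep]
}

#' Simulate a structural-specificity test field
#'
#' Builds co-registered test and reference channel images over a region mask,
#' with known fractions of supra-threshold ("labeled") pixels inside and
#' outside the region, for validating [structure_specificity()]. Labeled
#' pixels take a high intensity well above the Z = 3 threshold of the
#' background distribution.
#'
#' @param seed Integer seed.
#' @param size Image side in pixels; the region mask is the central disk.
#' @param inside_frac_test,inside_frac_ref Fraction of in-region pixels
#'   labeled in the test and reference channel.
#' @param outside_frac_test,outside_frac_ref Same, outside the region.
#' @param label_value Intensity of labeled pixels.
#' @return List with `test`, `ref` (matrices) and `mask` (logical matrix).
#' @export
simulate_specificity_field <- function(seed = 1L, size = 256,
                                       inside_frac_test = 0.2,
                                       inside_frac_ref = 0.1,
                                       outside_frac_test = 0.02,
                                       outside_frac_ref = 0.02,
                                       label_value = 100) {
  set.seed(seed)
  ctr <- (size + 1) / 2
  g <- expand.grid(row = seq_len(size), col = seq_len(size))
  mask <- matrix((g$row - ctr)^2 + (g$col - ctr)^2 <= (size / 4)^2, size, size)
  paint <- function(frac_in, frac_out) {
    img <- matrix(stats::rnorm(size^2, 10, 2), size, size)
    ins <- which(mask); outs <- which(!mask)
    img[sample(ins, round(frac_in * length(ins)))] <- label_value
    img[sample(outs, round(frac_out * length(outs)))] <- label_value
    img
  }
  list(test = paint(inside_frac_test, outside_frac_test),
       ref = paint(inside_frac_ref, outside_frac_ref),
       mask = mask)
}
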