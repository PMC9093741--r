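---
title: "Methods: quantifying inferior-olive activity from GCaMP6s imaging and paired recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying inferior-olive activity from GCaMP6s imaging and paired recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(olivetrace)
```

## The scientific problem

Inferior-olive (IO) neurons fire at very low rates (rarely above 0.2 Hz in
vitro) but each action potential carries rich waveform information: a fast
sodium spike rides on a calcium-carried depolarization plateau (the "calcium
shoulder", roughly 4-22 ms), and the duration of that shoulder — the *spike
width* — shapes the burst the axon delivers to the cerebellum as a climbing
fiber signal. Between spikes, many IO cells display 3-13 Hz subthreshold
membrane oscillations (STOs). Both features are visible, indirectly, in
somatic GCaMP6s fluorescence: each spike produces a calcium event (eCa) whose
*rise time* grows with the shoulder width, and STOs appear as small (~0.1-1 %
DFF) periodic fluorescence fluctuations.

`olivetrace` implements the full quantitative chain needed to exploit this:

1. **photometry** — raw camera counts to calibrated light power (fW),
   ROI-mean traces, F0 baselines and DFF;
2. **events** — slope-based eCa detection and waveform metrics;
3. **sto** — event excision, band-passing, Blackman-windowed Welch spectra
   and oscillating/non-oscillating classification in both modalities;
4. **ephys** — spike detection and shoulder-width measurement in
   membrane-voltage recordings, PCA + elbow k-means spike typing;
5. **calibration** — the linear rise-time-to-width mapping and burst
   spikelet counts;
6. **anatomy** — neuron/astrocyte soma classification, normalized transgene
   expression, structural specificity and labeling-density statistics;
7. **sim** — a synthetic-data generator that emulates the physiology and the
   camera statistics, with ground-truth manifests, used by every test.

## Photon-power calibration

Counts are mapped to power through a linear sensor model: `digital_max`
counts correspond to a full well of 600,000 electrons, each electron is
charged with 1.6e-19 J (the rounded constant, kept for reproducibility of the
published scale rather than the CODATA value), and multiplying by the frame
rate converts energy per frame to power:

\[
P = \mathrm{counts}\cdot\frac{\mathrm{full\ well}}{\mathrm{digital\ max}}
    \cdot 1.6\times10^{-19}\,\mathrm{J}\cdot f_s
\]

At full scale and 30 fps this gives exactly 2880 fW. The mapping is linear,
so ROI averaging and calibration commute, and recordings at different frame
rates land on one power scale. No background subtraction is applied anywhere.

```{r}
counts_to_power(fluor_trace(65535, frame_rate = 30), camera_model())$value
```

## Event detection and rise-time measurement

Events are detected from the z-scored instantaneous slope of the trace with a
threshold of 4 and a minimal peak-to-peak separation of 500 ms. Two numerical
choices matter at video rate:

* **Slope pre-smoothing** (`smooth_ms`, default 150 ms). At 30 fps the raw
  first difference is dominated by photon shot noise: a 3 % DFF event at
  F0 = 400 fW has a raw slope z-score of about 2 and would be undetectable.
  A short centered moving average restores the slope SNR; the onset estimate
  is compensated for the smoother's spread and refined to the last sample
  whose slope is indistinguishable from zero (within one robust SD — a
  literal "non-positive slope" rule walks arbitrarily far back through
  correlated smoothed noise). On noise-free waveforms onsets are exact; on
  noisy simulations the mean onset error is well under one frame.
* **Peak-time estimation** (`peak_smooth_ms`, default 200 ms). GCaMP6s
  transients have a flat, asymmetric top (alpha-function rise, ~1.5 s decay),
  so the argmax of a noisy trace is dragged late along the slow decay. The
  peak time is instead taken as the centroid of the *near-maximum plateau* —
  all samples within 1.5 noise SDs of the maximum, with both plateau edges
  interpolated at sub-frame resolution and the search bounded by the
  detection-stage peak. The peak *intensity* (F_peak) is read from the raw
  trace at the peak frame, so DFF amplitudes are not biased by smoothing.

F0 is the minimum of the 500 ms window before onset; the rise time is the
onset-to-peak interval; events closer than the minimal separation merge
keeping the larger peak (ties keep the earlier). Stacked events — a second
supra-threshold onset inside a rise segment — are flagged `"double"` rather
than silently dropped, replacing the manual curation step of a human analyst
with a reviewable rule.

```{r}
cfg <- sim_config(duration = 20, spike_times = c(4, 10, 16),
                  shoulder_widths = c(8, 12, 16), f0 = 800, seed = 21)
fw <- counts_to_power(simulate_fluorescence(cfg)$trace)
ev <- event_metrics(fw, detect_events(fw))
ev[, c("onset_s", "rise_time_ms", "dff_peak", "flag")]
autoplot(fw, events = ev)
```

## Subthreshold oscillations

STO spectra are Welch averages of Blackman-windowed periodograms with 2 s
segments and 50 % overlap — 0.5 Hz resolution on the 10 s acquisitions the
analysis is designed around. Before spectral analysis, each event window
(100 ms before onset to ~3 decay constants after) is excised and linearly
interpolated, suppressing the 0-3 Hz leakage of spike transients while
leaving the 3-12 Hz band intact; band-passing uses a zero-phase third-order
Butterworth filter, chosen for a flat passband with no phase distortion of
oscillation timing.

Two published thresholds classify cells as oscillating:

* voltage: 3-12 Hz band power above **1 mV² RMS**. `band_power` is the
  one-sided PSD integrated over the band, so a sinusoid of amplitude A
  contributes A²/2 — the scale on which the threshold is defined.
* fluorescence: band-limited STO amplitude above **0.12 % DFF** (the 5th
  percentile of electrophysiologically confirmed oscillators).

At realistic expression levels the camera shot-noise floor inside the band is
comparable to 0.12 % DFF, so the fluorescence amplitude estimator is
noise-corrected: power is summed over the spectral main lobe (peak ± 1.5 Hz),
the median in-band density outside that window is subtracted as the noise
floor, and amplitude is `sqrt(2 P)`. Noise-only traces then report ~0.04 %
rather than sitting above the threshold. Even so, resolving STOs demands high
indicator expression: the paired-modality simulations use F0 = 1500 fW
(below 60 % of the full-well-equivalent power), mirroring the observation
that STO imaging requires stronger expression than spike imaging. The
simulated fluorescence STO gain is 0.00085 DFF per mV of membrane
oscillation, the value that makes the two published thresholds describe the
same cell population.

```{r}
cfg <- sim_config(duration = 10, sto_amp = 3, sto_freq = 6, f0 = 1500,
                  sto_dff = 0.00085 * 3, vm_noise_sd = 0.5, seed = 7)
rv <- welch_psd(simulate_vm(cfg)$trace)
rf <- welch_psd(dff(counts_to_power(simulate_fluorescence(cfg)$trace), 1500))
c(vm_peak = rv$peak_freq, fluo_peak = rf$peak_freq,
  ratio = frequency_match(rv, rf))
autoplot(rf)
```

The mixed published unit ("0.1 % DFF corresponding to 0.00024 fW²/Hz RMS")
conflates amplitude with spectral density; the package reports `band_power`
and `amplitude` separately and asserts no conversion between them.

## Spike waveforms and typing

Vm spikes are detected where the depolarization exceeds the trace median by
10 mV; the initiation point is the last sample before the rise crosses
median + 2 mV (median baseline and a low crossing level are robust to ongoing
STOs). The spike width is the contiguous time above baseline + 10 mV,
measured between sub-sample interpolated crossings; the +10 mV criterion is
relative to the pre-spike baseline, not absolute voltage, making the width
invariant to offsets. Waveforms that never reach the threshold are spikelets
(gap-junction echoes of neighbours' spikes) and return width 0 with a flag.

Spike typing follows the standard recipe: mean-centered PCA of the raw
aligned waveforms (no z-scoring — amplitude differences are informative),
k-means on the first two component scores with 10 restarts under a fixed
seed, and k chosen at the elbow of the within-cluster sum-of-squares curve
(maximal perpendicular distance to the chord between k = 1 and k = k_max on
the normalized curve). Well-separated clusters are recovered exactly. A known
limitation: on *unstructured* data (a single Gaussian cloud) the WSS curve is
smooth and convex (~1/k) and has no true elbow; the chord criterion then
lands at an intermediate k rather than 1. Elbow selection answers "where does
the curve bend", not "is there any structure" — users should inspect the
`wss` curve before trusting k on weakly clustered data.

## The rise-time-to-width calibration

Paired imaging/patch recordings show the eCa rise time grows linearly with
spike width: about 6 ms of width per 100 ms of rise time, with the shortest
events (200 ms rise time) corresponding to 4-5 ms spikes. Taking the 4.5 ms
midpoint gives the default model

\[ w(\mathrm{ms}) = 0.06\cdot RT(\mathrm{ms}) - 7.5 \]

so the mean in-vivo rise time of 351 ms maps to 13.6 ms, matching the
reported in-vivo width of 13.7 ± 0.7 ms. Rise times under 150 ms fall outside
the domain of normal IO spikes (they mark "short IO spikes", sIO-s) and are
flagged. `fit_calibration()` estimates the same line from user data by OLS,
with `tidy()`/`glance()` accessors.

Assuming 270 Hz axonal burst firing, a spike of width w carries
`1 + floor(w * 270 / 1000)` spikelets — 4 at the mean in-vivo width,
inside the published 4-5 expectation. No single floor/round rule also yields
5 at the extreme 21.8 ms width the same passage mentions, so the counting
rule is exposed as an argument rather than asserted as the authors'
arithmetic.

```{r}
tidy(default_calibration())
rt_to_width(c(200, 300, 351))
expected_spikelet_count(13.7)
```

## Anatomy quantification

Somata are classified as neurons by either criterion the histology supports:
normalized NeuN radial intensity exceeding 20 % (strictly) within a 2 um
radius, or soma area strictly above 100 um² — the area threshold the
percentiles of the two populations straddle (5th percentile of neurons above,
95th of astrocytes below). Expression is normalized per soma as EGFP /
tdTomato; construct preference is the percent excess of neuron enrichment
over astrocyte enrichment against a control virus; structural specificity
thresholds each channel at mean + 3 SD of its whole-image histogram
(configurable to background-region statistics) and reports extent and
intensity ratios inside and outside the region mask separately — whether the
original analysis combined them into one score is not stated, so both are
kept. Compartments with no supra-threshold reference pixels report `NA`, not
zero.

## The synthetic-data generator

`simulate_vm()` builds phenomenological waveforms: baseline (−55 mV) + STO
sinusoid + spikes (1 ms triangular sodium peak to +80 mV, +20 mV shoulder
plateau of configured width, −10 mV AHP decaying over ~50 ms) + 10 ms
half-sine spikelets + Gaussian noise, at 10 kHz — sufficient for
millisecond-resolution widths without the cost of the original 50 kHz
acquisition. `simulate_fluorescence()` runs the forward model: transients
with alpha-function rises peaking at the rise time implied by the shoulder
width (the calibration used in inverse), single-exponential 1.5 s decays,
additive superposition, peak DFF of 0.35 % per ms of width — a free constant
chosen so a ~14 ms spike yields ~5 % DFF, in the middle of the 1-12 % in-vivo
range; no absolute fluorescence-per-ms-of-width gain has been measured, so this constant is a stated free parameter. Power converts to expected
electrons per frame, then Poisson shot noise, 130 e⁻ Gaussian dark noise and
quantization produce counts. `simulate_anatomy()` renders disk somata with
truncated-normal areas (neurons above 102 um², astrocytes below 98 um²) so
the published percentile straddle is reproduced *and* area classification is
exactly separable — a deliberate idealization.

What the generator does **not** emulate: motion, photobleaching, neuropil
contamination, GCaMP saturation at large calcium loads, conductance-based
spike dynamics or gap-junction network interactions. Passing tests therefore
demonstrate the correctness of the measurement chain under the stated noise
model, not robustness to every artifact of real preparations.

## Problem sizes and study conditions

The test-suite simulations use 10-60 s traces at 30 fps (10 kHz for Vm),
10 cells per condition, 50-100 events or 50 paired cells per experiment —
sizes at which every quantity under test is statistically stable while the
whole suite runs in minutes. Expression levels follow the physiology:
detection performance is evaluated at F0 = 400 fW with events of at least 3 %
DFF; width recovery (MAE ≤ 2 ms over 5-20 ms shoulders) at F0 = 800 fW, the
middle of the expression range reported as optimal for spike SNR; STO
classification at F0 = 1500 fW. Rank agreement between rise time and shoulder
width is evaluated over the full physiological 4.5-22 ms range. At the low
end of the expression range the smallest (~5 ms, 1.75 % DFF) events approach
the z = 4 detection limit and a fraction are missed; this mirrors the
real detectability limit rather than a defect of the detector.

## Reproducibility

Every simulation takes an integer seed and is bit-identical under it. The
pipeline drivers (`run_imaging_pipeline()`, `run_anatomy_pipeline()`) embed
the seed and a configuration hash in their JSON summaries, and re-runs with
the same configuration produce byte-identical outputs.
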