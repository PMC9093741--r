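# olivetrace

Analysis of inferior-olive (IO) neuron activity from 1-photon GCaMP6s
calcium imaging and paired whole-cell patch-clamp recordings, for
experimenters who image deep brainstem nuclei at video rate and want
spike-waveform information back out of slow calcium indicators.

IO neurons fire rarely but informatively: each action potential carries a
calcium-shoulder plateau of 4–22 ms whose duration ("spike width") shapes
the climbing-fiber burst sent to the cerebellum, and many cells oscillate
subthreshold at 3–13 Hz (STOs). Both signatures leak into somatic GCaMP6s
fluorescence. `olivetrace` implements the measurement chain that recovers
them:

* **Photon-power calibration.** Raw counts → light power:
  `P = counts · (full_well / digital_max) · 1.6e-19 J · f_s`,
  with the published sensor constants (600,000 e⁻ full well, 130 e⁻ dark
  noise); full scale at 30 fps is exactly 2880 fW.
* **Calcium-event (eCa) detection** by maximal instantaneous slope increase
  (robust z ≥ 4, minimal 500 ms peak-to-peak separation), with F₀ (minimum
  of the 500 ms pre-onset window), rise time RT (onset → transient peak, at
  sub-frame resolution) and DFF peak per event.
* **STO spectral analysis**: event excision, zero-phase 3–12 Hz band-pass,
  Blackman-windowed Welch PSD; cells classify as oscillating above
  1 mV² RMS (voltage) or 0.12 % DFF (fluorescence, noise-floor-corrected).
* **Spike typing**: widths from the +10 mV-above-baseline crossing of
  aligned Vm waveforms, PCA of the raw waveforms, k-means with elbow
  selection.
* **Rise-time → width calibration**: `w = 0.06·RT − 7.5` (ms) — 6 ms of
  width per 100 ms of rise time, anchored at 200 ms ↦ 4.5 ms — plus OLS
  fitting from paired data (`fit_calibration()`, `tidy()`, `glance()`) and
  expected spikelet counts at 270 Hz burst firing.
* **Anatomy quantification**: neuron/astrocyte soma classification (NeuN
  radial profile > 20 % within 2 µm, or area > 100 µm²), normalized
  EGFP/tdTomato expression, Z = 3 structural specificity, nearest-neighbour
  spacing.
* **A synthetic-data generator** (`simulate_vm()`, `simulate_fluorescence()`,
  `simulate_anatomy()`) that emulates the physiology and the camera's
  Poisson/Gaussian noise, with ground-truth manifests — every quantitative
  claim in the test suite is validated against it.

## Worked example

Simulate one cell with three spikes of known shoulder widths (8, 12, 16 ms),
push the fluorescence through the camera model, detect events, and read the
widths back through the calibration:

```r
library(olivetrace)

cfg <- sim_config(duration = 20, spike_times = c(4, 10, 16),
                  shoulder_widths = c(8, 12, 16), f0 = 800, seed = 21)
fw <- counts_to_power(simulate_fluorescence(cfg)$trace)
ev <- event_metrics(fw, detect_events(fw))
ev[, c("onset_s", "rise_time_ms", "f0", "dff_peak")]
#> # A tibble: 3 × 4
#>   onset_s rise_time_ms    f0 dff_peak
#>     <dbl>        <dbl> <dbl>    <dbl>
#> 1       4         300.  796.   0.0316
#> 2      10         343.  796.   0.0490
#> 3      16         398.  798.   0.0611

round(rt_to_width(ev$rise_time_ms), 1)
#> [1] 10.5 13.1 16.4
expected_spikelet_count(rt_to_width(ev$rise_time_ms))
#> [1] 3 4 5
```

All three events are found at their true onsets; rise times of 300–400 ms
translate to widths within ~2 ms of the generated 8/12/16 ms shoulders
(frame quantization at 30 fps dominates the error), and the implied axonal
bursts carry 3–5 spikelets. `autoplot(fw, events = ev)` draws the trace with
onsets and peaks marked; `welch_psd()` + `autoplot()` does the same for STO
spectra. `run_imaging_pipeline()` chains the whole analysis over a
population of cells and writes events/STO/width tables plus a seeded,
hash-stamped JSON summary.

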