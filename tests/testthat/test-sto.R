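test_that("event excision removes spike windows without altering length", {
  tr <- fluor_trace(rep(400, 300), frame_rate = 30)
  e0 <- detect_events(tr)
  expect_equal(excise_events(tr, e0)$value, tr$value)
  # one event in an otherwise-constant trace interpolates back to constant
  v <- rep(400, 300); v[150:200] <- 450
  ev <- tibble::tibble(roi_id = "r", onset_frame = 150L, peak_frame = 160L,
                       onset_s = 149 / 30, peak_s = 159 / 30,
                       peak_value = 450, flag = "ok")
  out <- excise_events(fluor_trace(v, 30), ev)
  expect_equal(out$value, rep(400, 300))
  expect_equal(nrow(out), 300)
  # events covering most of the trace are rejected
  ev_all <- tibble::tibble(roi_id = "r",
                           onset_frame = as.integer(seq(1, 280, by = 20)),
                           peak_frame = as.integer(seq(5, 284, by = 20)),
                           onset_s = 0, peak_s = 0, peak_value = 1,
                           flag = "ok")
  expect_error(excise_events(fluor_trace(v, 30), ev_all), "80%")
})

test_that("excision suppresses low-band spike leakage but keeps the STO", {
  t <- (0:1799) / 30
  sto <- 0.004 * sin(2 * pi * 7 * t)
  trans <- numeric(1800)
  rel <- t - 8
  trans[rel >= 0 & rel <= 0.3] <- (rel[rel >= 0 & rel <= 0.3] / 0.3) *
    exp(1 - rel[rel >= 0 & rel <= 0.3] / 0.3)
  trans[rel > 0.3] <- exp(-(rel[rel > 0.3] - 0.3) / 1.5)
  v <- 400 * (1 + sto + 0.08 * trans)
  tr <- fluor_trace(v, 30)
  ev <- tibble::tibble(roi_id = "r", onset_frame = 241L, peak_frame = 250L,
                       onset_s = 8, peak_s = 8.3, peak_value = max(v),
                       flag = "ok")
  exc <- excise_events(tr, ev)
  low_mass <- function(x) {
    s <- welch_psd(x, sto_params(band = c(0.5, 3)))
    s$band_power
  }
  expect_lt(low_mass(exc), 0.5 * low_mass(tr))
  p1 <- welch_psd(tr); p2 <- welch_psd(exc)
  expect_equal(p2$peak_freq, p1$peak_freq)
  pk <- function(r) max(r$spectrum$psd[r$spectrum$freq >= 3 &
                                       r$spectrum$freq <= 12])
  expect_lt(abs(pk(p2) - pk(p1)) / pk(p1), 0.10)
})

test_that("the band-pass filter has the required response", {
  fs <- 30
  t <- (0:599) / fs
  # constant in, ~zero out
  z <- bandpass_trace(fluor_trace(rep(5, 600), fs))
  expect_lt(max(abs(z$value)), 1e-9 * 5)
  # 7 Hz passes nearly unattenuated
  s7 <- bandpass_trace(fluor_trace(10 + sin(2 * pi * 7 * t), fs))
  mid <- 150:450
  expect_gte(max(s7$value[mid]), 0.9)
  # 0.5 Hz is strongly attenuated
  s05 <- bandpass_trace(fluor_trace(10 + sin(2 * pi * 0.5 * t), fs))
  expect_lte(max(abs(s05$value[mid])), 0.1)
  # a 12 Hz band edge needs more than 24 Hz sampling
  expect_error(bandpass_trace(fluor_trace(rep(1, 100), 24)), "Nyquist")
})

test_that("Welch PSD satisfies Parseval and localizes sinusoids", {
  set.seed(10)
  x <- stats::rnorm(3000)
  spec <- welch_psd(x, fs = 30)
  df <- spec$spectrum$freq[2] - spec$spectrum$freq[1]
  expect_lt(abs(sum(spec$spectrum$psd) * df - stats::var(x)) / stats::var(x),
            0.10)
  t <- (0:599) / 30
  r6 <- welch_psd(fluor_trace(100 + 3 * sin(2 * pi * 6 * t), 30))
  expect_lte(abs(r6$peak_freq - 6), 0.5)
  # dominance: 6 Hz at twice the 9 Hz amplitude wins the band peak
  r69 <- welch_psd(fluor_trace(100 + 2 * sin(2 * pi * 6 * t) +
                                 sin(2 * pi * 9 * t), 30))
  expect_lte(abs(r69$peak_freq - 6), 0.5)
  expect_true(all(spec$spectrum$psd >= 0))
  expect_error(welch_psd(fluor_trace(rep(1, 30), 30)), "segment")
})

test_that("oscillation classification follows the published thresholds", {
  # zero trace is non-oscillating in both modalities
  z <- welch_psd(vm_trace(rep(-55, 20000), 10000))
  expect_false(classify_oscillating(z, modality = "vm"))
  # a 2 mV STO carries 2 mV^2 band power, above the 1 mV^2 threshold
  cfg <- sim_config(duration = 10, sto_amp = 2, sto_freq = 6,
                    vm_noise_sd = 0.5, seed = 6)
  r <- welch_psd(simulate_vm(cfg)$trace)
  expect_lt(abs(r$band_power - 2) / 2, 0.15)
  expect_true(classify_oscillating(r, modality = "vm"))
  # paired Vm / fluorescence of one clear oscillator agree
  cfgp <- sim_config(duration = 10, sto_amp = 3, sto_freq = 6,
                     vm_noise_sd = 0.5, f0 = 1500,
                     sto_dff = 0.00085 * 3, seed = 7)
  rv <- welch_psd(simulate_vm(cfgp)$trace)
  d <- dff(counts_to_power(simulate_fluorescence(cfgp)$trace), 1500)
  rf <- welch_psd(d)
  expect_true(classify_oscillating(rv, modality = "vm"))
  expect_true(classify_oscillating(rf, modality = "fluorescence"))
  expect_lte(abs(frequency_match(rv, rf) - 1), 0.5 / 6 + 1e-9)
})

test_that("frequency matching is undefined for non-oscillating cells", {
  t <- (0:19999) / 10000
  quiet <- welch_psd(vm_trace(-55 + 0.1 * sin(2 * pi * 6 * t), 10000))
  osc <- welch_psd(vm_trace(-55 + 5 * sin(2 * pi * 6 * t), 10000))
  expect_equal(frequency_match(osc, osc), 1)
  expect_error(frequency_match(quiet, osc), "non-oscillating")
})

test_that("band power grows monotonically with simulated STO amplitude", {
  bp <- vapply(c(0.5, 1, 2, 4), function(a) {
    cfg <- sim_config(duration = 10, sto_amp = a, sto_freq = 6,
                      vm_noise_sd = 0.5, seed = 8)
    welch_psd(simulate_vm(cfg)$trace)$band_power
  }, numeric(1))
  expect_true(all(diff(bp) > 0))
})

test_that("peak frequency is recovered within one Welch bin across the band", {
  for (f in c(4, 6, 8, 10, 12)) {
    cfg <- sim_config(duration = 10, sto_amp = 3, sto_freq = f,
                      vm_noise_sd = 0.5, seed = 20 + f)
    r <- welch_psd(simulate_vm(cfg)$trace)
    expect_lte(abs(r$peak_freq - f), 0.5)
  }
})
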