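test_that("constant and zero-variance traces yield no events", {
  tr <- fluor_trace(rep(500, 120), frame_rate = 30)
  expect_equal(nrow(detect_events(tr)), 0)
  expect_error(detect_events(fluor_trace(rep(1, 30), 30)), "2 s")
})

test_that("a step of ten slope-SDs is detected once, at the step frame", {
  set.seed(7)
  sigma <- 1
  v <- stats::rnorm(300, 100, sigma)
  step_frame <- 150
  v[step_frame:300] <- v[step_frame:300] + 10 * sigma * sqrt(2)
  ev <- detect_events(fluor_trace(v, 30))
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$onset_frame - step_frame), 1)
})

test_that("events with peaks closer than the separation merge to the larger", {
  # two identical transients 300 ms apart must merge into one event
  t <- (0:449) / 30
  shape <- function(t0) {
    s <- numeric(length(t)); rel <- t - t0
    up <- rel >= 0 & rel <= 0.3; dn <- rel > 0.3
    s[up] <- (rel[up] / 0.3) * exp(1 - rel[up] / 0.3)
    s[dn] <- exp(-(rel[dn] - 0.3) / 1.5)
    s
  }
  set.seed(3)
  v <- 400 * (1 + 0.05 * shape(5) + 0.05 * shape(5.3)) +
    stats::rnorm(450, 0, 0.4)
  ev <- detect_events(fluor_trace(v, 30))
  expect_equal(nrow(ev), 1)
  # and with wide spacing both survive, peaks >= 500 ms apart
  v2 <- 400 * (1 + 0.05 * shape(4) + 0.05 * shape(9)) +
    stats::rnorm(450, 0, 0.4)
  ev2 <- detect_events(fluor_trace(v2, 30))
  expect_equal(nrow(ev2), 2)
  expect_gte(diff(ev2$peak_s), 0.5)
})

test_that("inter-peak separation holds on simulated bursts of events", {
  cfg <- sim_config(duration = 30, spike_times = seq(2, 28, by = 0.9),
                    shoulder_widths = rep(12, 29), f0 = 800, seed = 13)
  fw <- counts_to_power(simulate_fluorescence(cfg)$trace)
  ev <- detect_events(fw)
  if (nrow(ev) > 1) expect_true(all(diff(ev$peak_s) >= 0.5))
})

test_that("onsets are exact on noise-free transients", {
  cfg <- sim_config(duration = 20, spike_times = c(4, 10, 16),
                    shoulder_widths = c(8, 12, 16), f0 = 400, seed = 1)
  tr <- simulate_fluorescence(cfg, noise = FALSE)$trace
  # add a whisper of noise so the slope MAD is defined, then require
  # frame-accurate onsets
  set.seed(8)
  v <- tr$value + stats::rnorm(nrow(tr), 0, 1e-4 * mean(tr$value))
  ev <- detect_events(fluor_trace(v, 30))
  expect_equal(nrow(ev), 3)
  expect_true(all(abs(ev$onset_s - c(4, 10, 16)) <= 1 / 30 + 1e-9))
})

test_that("event metrics compute rise time, F0, peak and DFF", {
  # ramp spanning 10 frames at 30 fps -> rise time 333 ms
  v <- c(rep(400, 100), seq(402, 420, length.out = 10),
         seq(418, 400, length.out = 10), rep(400, 100))
  tr <- fluor_trace(v, 30)
  ev <- tibble::tibble(roi_id = "r", onset_frame = 100L, peak_frame = 110L,
                       onset_s = 99 / 30, peak_s = 109 / 30,
                       peak_value = 420, flag = "ok")
  m <- event_metrics(tr, ev)
  expect_equal(m$rise_time_ms, 10 / 30 * 1000, tolerance = 0.01)
  expect_equal(m$f0, 400)
  expect_equal(m$f_peak, 420)
  # dff arithmetic: 400 -> 420 is 5 %
  expect_equal(m$dff_peak, 0.05)
  expect_false(m$truncated)
  # flat "event" has zero rise and zero dff
  flat <- fluor_trace(rep(400, 160), 30)
  ev0 <- tibble::tibble(roi_id = "r", onset_frame = 60L, peak_frame = 60L,
                        onset_s = 59 / 30, peak_s = 59 / 30,
                        peak_value = 400, flag = "ok")
  m0 <- event_metrics(flat, ev0)
  expect_equal(m0$dff_peak, 0)
  # events whose window leaves the trace are flagged truncated
  evT <- tibble::tibble(roi_id = "r", onset_frame = 155L, peak_frame = 158L,
                        onset_s = 154 / 30, peak_s = 157 / 30,
                        peak_value = 400, flag = "ok")
  expect_true(event_metrics(flat, evT)$truncated)
})

test_that("rise time grows monotonically with ground-truth shoulder width", {
  widths_all <- seq(4.5, 22, length.out = 50) # full physiological range
  rts <- c(); ws <- c()
  for (cell in 1:10) {
    widths <- widths_all[seq(cell, 50, by = 10)] # 5 distinct widths per cell
    cfg <- sim_config(duration = 33, spike_times = seq(3, 31, by = 7),
                      shoulder_widths = widths, f0 = 800, seed = 400 + cell)
    fw <- counts_to_power(simulate_fluorescence(cfg)$trace)
    ev <- event_metrics(fw, detect_events(fw))
    j <- match_events(ev, cfg$spike_times)
    ok <- !is.na(j)
    rts <- c(rts, ev$rise_time_ms[j[ok]])
    ws <- c(ws, widths[ok])
  }
  expect_gte(length(rts), 40)
  expect_gt(stats::cor(ws, rts, method = "spearman"), 0.9)
})

test_that("aligned event matrices respect padding and averaging rules", {
  v <- rep(400, 300); v[150:160] <- 450
  tr <- fluor_trace(v, 30)
  ev <- tibble::tibble(roi_id = "r", onset_frame = 150L, peak_frame = 155L,
                       onset_s = 149 / 30, peak_s = 154 / 30,
                       peak_value = 450, flag = "ok")
  m <- align_events(tr, ev, pre_ms = 500, post_ms = 1000)
  expect_equal(nrow(m), 1)
  expect_equal(m[1, ], v[135:180], ignore_attr = TRUE)
  # identical events give zero column variance
  ev2 <- dplyr::bind_rows(ev, ev)
  m2 <- align_events(tr, ev2, 500, 1000)
  expect_equal(apply(m2, 2, stats::var), rep(0, ncol(m2)),
               ignore_attr = TRUE)
  # out-of-bounds events are NA-padded and excluded from averages
  ev3 <- dplyr::bind_rows(ev, dplyr::mutate(ev, onset_frame = 5L))
  m3 <- align_events(tr, ev3, 500, 1000)
  expect_equal(attr(m3, "complete"), c(TRUE, FALSE))
  expect_true(anyNA(m3[2, ]))
  expect_equal(average_aligned(m3), m3[1, ], ignore_attr = TRUE)
  # empty event list gives an empty matrix
  e0 <- detect_events(fluor_trace(rep(1, 120), 30))
  expect_equal(nrow(align_events(tr, e0)), 0)
})

test_that("the mean of aligned noisy copies recovers the template", {
  set.seed(42)
  tmpl <- 400 * (1 + 0.05 * c(rep(0, 15), (1:30) / 30, exp(-(1:45) / 45)))
  n <- 100
  sd_n <- 2
  traces <- matrix(rep(tmpl, each = n), nrow = n) +
    stats::rnorm(n * length(tmpl), 0, sd_n)
  # build one long trace per copy and align on the known onset
  onsets <- rep(16L, n)
  m <- matrix(NA_real_, n, 61)
  for (i in 1:n) {
    tr <- fluor_trace(traces[i, ], 30)
    ev <- tibble::tibble(roi_id = "r", onset_frame = onsets[i],
                         peak_frame = 45L, onset_s = 0.5, peak_s = 1.5,
                         peak_value = 1, flag = "ok")
    m[i, ] <- align_events(tr, ev, pre_ms = 500, post_ms = 1500)[1, ]
  }
  avg <- colMeans(m)
  sem <- sd_n / sqrt(n)
  expect_true(all(abs(avg - tmpl[1:61]) < 3 * sem + 1e-9))
})
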