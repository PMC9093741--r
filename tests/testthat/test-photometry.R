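test_that("counts_to_power reproduces the closed-form power scale", {
  cam <- camera_model()
  tr <- fluor_trace(c(0, 65535), frame_rate = 30)
  p <- counts_to_power(tr, cam)
  expect_identical(trace_unit(p), "fW")
  expect_equal(p$value[1], 0)
  # full-scale counts at 30 fps: 600000 e- x 1.6e-19 J x 30 /s = 2880 fW
  expect_equal(p$value[2], 2880)
  # linear in frame rate: same counts at 60 fps give exactly twice the power
  tr60 <- fluor_trace(c(0, 65535), frame_rate = 60)
  expect_equal(counts_to_power(tr60, cam)$value[2], 2 * p$value[2])
})

test_that("counts_to_power is linear and monotonic in counts", {
  cam <- camera_model()
  x <- seq(0, 60000, length.out = 25)
  p <- counts_to_power(fluor_trace(x, 30), cam)$value
  expect_true(all(diff(p) > 0))
  p2 <- counts_to_power(fluor_trace(2 * x[x <= 30000], 30), cam)$value
  expect_equal(p2, 2 * p[x <= 30000])
})

test_that("counts round-trip through power and saturation is rejected", {
  cam <- camera_model()
  tr <- fluor_trace(c(10, 5000, 65535), frame_rate = 30)
  back <- power_to_counts(counts_to_power(tr, cam), cam)
  expect_equal(back$value, tr$value, tolerance = 1e-12)
  expect_error(counts_to_power(fluor_trace(70000, 30), cam), "digital_max")
})

test_that("ROI extraction averages pixels and commutes with calibration", {
  set.seed(1)
  img <- array(stats::runif(8 * 8 * 6, 0, 1000), dim = c(8, 8, 6))
  # uniform frame returns the frame value
  uni <- array(rep(c(7, 9), each = 64), dim = c(8, 8, 2))
  mask <- matrix(TRUE, 8, 8)
  expect_equal(extract_roi_trace(uni, mask, 30)$value, c(7, 9))
  # single-pixel ROI returns that pixel's series
  one <- data.frame(row = 3, col = 5)
  expect_equal(extract_roi_trace(img, one, 30)$value, img[3, 5, ])
  # two-pixel ROI averages
  two <- data.frame(row = c(1, 2), col = c(1, 1))
  expect_equal(extract_roi_trace(img, two, 30)$value,
               (img[1, 1, ] + img[2, 1, ]) / 2)
  # averaging commutes with the linear counts-to-power map
  cam <- camera_model()
  roi <- matrix(FALSE, 8, 8); roi[2:4, 2:4] <- TRUE
  a <- counts_to_power(extract_roi_trace(img, roi, 30), cam)$value
  per_pixel <- apply(img, 3, function(fr) {
    mean(counts_to_power(fluor_trace(fr[roi], 30), cam)$value)
  })
  expect_equal(a, per_pixel, tolerance = 1e-9)
  expect_error(extract_roi_trace(img, matrix(FALSE, 8, 8), 30), "empty")
})

test_that("baseline F0 is the pre-onset window minimum with an edge rule", {
  tr <- fluor_trace(rep(5, 60), frame_rate = 30)
  expect_equal(baseline_f0(tr, 40), 5)
  v <- rep(10, 60); v[32] <- 3
  expect_equal(baseline_f0(fluor_trace(v, 30), 40), 3)
  # window is 500 ms = 15 frames; a dip outside it is ignored
  v2 <- rep(10, 60); v2[10] <- 1
  expect_equal(baseline_f0(fluor_trace(v2, 30), 40), 10)
  # onset closer than the window: minimum over the available prefix
  v3 <- c(4, 8, 2, 9, 7, rep(10, 55))
  expect_equal(baseline_f0(fluor_trace(v3, 30), 6), 2)
  expect_error(baseline_f0(tr, 1), "precede")
  # never exceeds the minimum of any sub-window
  set.seed(2)
  v4 <- stats::runif(90)
  tr4 <- fluor_trace(v4, 30)
  expect_true(baseline_f0(tr4, 60) <= min(v4[50:59]))
})

test_that("dff normalizes against the baseline and rejects bad baselines", {
  tr <- fluor_trace(rep(400, 90), frame_rate = 30)
  expect_equal(dff(tr, 400)$value, rep(0, 90))
  v <- rep(400, 90); v[50] <- 800
  expect_equal(dff(fluor_trace(v, 30), 400)$value[50], 1.0)
  expect_identical(trace_unit(dff(tr, 400)), "dff")
  expect_error(dff(tr, 0), "positive")
  expect_error(dff(tr, -5), "positive")
})

test_that("TIFF stacks round-trip into the image-series array layout", {
  skip_if_not_installed("tiff")
  set.seed(3)
  counts <- array(sample(0:65535, 6 * 6 * 4), dim = c(6, 6, 4))
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(1:4, function(i) counts[, , i] / 65535), f,
                  bits.per.sample = 16)
  back <- read_image_stack(f)
  expect_equal(dim(back), c(6, 6, 4))
  expect_equal(back, counts, ignore_attr = TRUE)
  # and the recovered counts feed straight into ROI extraction
  roi <- matrix(TRUE, 6, 6)
  expect_equal(extract_roi_trace(back, roi, 30)$value,
               apply(counts, 3, mean))
})

test_that("trace CSV round trip preserves values and rates", {
  tr <- fluor_trace(stats::rnorm(50, 1000, 10), frame_rate = 30)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- read_trace_csv(f)
  expect_equal(back$value, tr$value, tolerance = 1e-6)
  expect_equal(frame_rate(back), 30, tolerance = 1e-6)
  vt <- vm_trace(stats::rnorm(2000, -55, 1), sampling_rate = 10000)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(vt, f2)
  expect_equal(read_trace_csv(f2)$vm, vt$vm, tolerance = 1e-6)
})
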