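test_that("baseline averaging is the voxelwise mean of baseline frames", {
  d <- c(4, 4, 4)
  arr <- array(100, dim = c(d, 5))
  vol <- volume4d(arr, c(0.1, 0.1, 0.15), c(-24, -12, 0, 12, 24), 3)
  expect_equal(average_baseline(vol), array(100, dim = d))
  arr[2, 2, 2, 1:3] <- c(90, 100, 110)
  vol <- volume4d(arr, c(0.1, 0.1, 0.15), c(-24, -12, 0, 12, 24), 3)
  expect_equal(average_baseline(vol)[2, 2, 2], 100)
  # oracle: an independent reduction path over a noisy phantom
  ph <- generate_dce_phantom(demo_phantom_spec(noise_sd = 2, seed = 3))
  B <- average_baseline(ph$volume)
  B2 <- apply(ph$volume$data[, , , 1:3], 1:3, mean)
  expect_equal(B, B2, tolerance = 1e-12)
})

test_that("difference images implement I - B with linear scaling", {
  d <- c(4, 4, 4)
  arr <- array(100, dim = c(d, 4))
  arr[, , , 4] <- 105
  vol <- volume4d(arr, c(0.1, 0.1, 0.15), c(-12, 0, 12, 24), 2)
  expect_equal(difference_image(vol, 3), array(0, dim = d))
  expect_equal(difference_image(vol, 4), array(5, dim = d))
  expect_error(difference_image(vol, 9), "out of range")
  expect_error(difference_image(vol, 1), "post-baseline")
  # linearity: scaling the series scales D identically
  vol2 <- volume4d(arr * 3, c(0.1, 0.1, 0.15), c(-12, 0, 12, 24), 2)
  expect_equal(difference_image(vol2, 4), 3 * difference_image(vol, 4))
})

test_that("ROI difference at the half-maximum time equals Imax/200 of baseline", {
  sp <- demo_phantom_spec(frame_times = c(-24, -12, 0, 39.66, 90))
  ph <- generate_dce_phantom(sp)
  mask <- phantom_roi_mask(ph)
  idx <- which(mask$labels == 1)
  D <- difference_image(ph$volume, 4)
  B <- average_baseline(ph$volume)
  expect_equal(mean(D[idx]) / mean(B[idx]), 60.17 / 200, tolerance = 1e-10)
})

test_that("ROI extraction reports percent change from baseline", {
  d <- c(4, 4, 4)
  arr <- array(100, dim = c(d, 4))
  arr[, , , 4] <- 160
  vol <- volume4d(arr, c(0.1, 0.1, 0.15), c(-12, 0, 12, 24), 2)
  labels <- array(0L, dim = d); labels[2:3, 2:3, 2:3] <- 1L
  ts <- extract_roi_timeseries(vol, roi_mask(labels, list(`1` = "roi")))
  expect_equal(ts$pct_change, c(0, 0, 0, 60))
  expect_equal(unique(ts$n_voxels), 8L)
  # empty label is an error naming the label
  labels2 <- labels; labels2[labels2 == 1L] <- 2L
  bad <- roi_mask(labels2, list(`1` = "gone"))
  expect_error(extract_roi_timeseries(vol, bad), "gone")
})

test_that("noiseless phantom time series match the generating curves", {
  ph <- generate_dce_phantom(demo_phantom_spec())
  ts <- extract_roi_timeseries(ph$volume, phantom_roi_mask(ph))
  truth <- ifelse(ts$time_min > 0,
                  sigmoid_model(sigmoid_params(60.17, 39.66, 10),
                                ts$time_min), 0)
  expect_lt(max(abs(ts$pct_change - truth)), 0.1)
})

test_that("registration recovers injected translations", {
  ph <- generate_dce_phantom(demo_phantom_spec())
  B <- average_baseline(ph$volume)
  # no motion: estimated shifts at zero
  expect_lt(max(abs(estimate_shift(B, B))), 1e-3)
  # integer shift recovered
  s <- estimate_shift(glymphkit:::shift_volume(B, c(2, -1, 0)), B)
  expect_equal(s, c(2, -1, 0), tolerance = 0.05)
  # sub-voxel shift recovered within a quarter voxel
  s2 <- estimate_shift(glymphkit:::shift_volume(B, c(0.4, 0, 0)), B)
  expect_lt(max(abs(s2 - c(0.4, 0, 0))), 0.25)
})

test_that("series registration realigns a moving phantom and flags dead frames", {
  sp <- demo_phantom_spec(motion_amplitude = 2, noise_sd = 1, seed = 21)
  ph <- generate_dce_phantom(sp)
  reg <- register_series(ph$volume)
  err <- as.matrix(reg$shifts[, c("dx", "dy", "dz")]) -
    as.matrix(ph$applied_shifts[, c("dx", "dy", "dz")])
  expect_lt(max(abs(err)), 0.5)
  expect_false(any(reg$shifts$failed))
  # all-zero frame passes through unshifted with a failure flag
  arr <- ph$volume$data
  arr[, , , 5] <- 0
  vol <- volume4d(arr, ph$volume$voxel_size, ph$volume$frame_times,
                  ph$volume$n_baseline)
  reg2 <- register_series(vol)
  expect_true(reg2$shifts$failed[5])
  expect_equal(reg2$volume$data[, , , 5], arr[, , , 5])
})

test_that("bias correction estimates the field from baseline only", {
  # flat phantom: estimated field constant within tolerance
  flat <- generate_dce_phantom(demo_phantom_spec(baseline_structure = 0))
  bc <- bias_correct(flat$volume)
  expect_lt(diff(range(bc$field)), 0.01)
  # known quadratic field: baseline coefficient of variation drops >= 10x
  sp <- demo_phantom_spec(baseline_structure = 0, bias_amplitude = 1.2)
  ph <- generate_dce_phantom(sp)
  bc2 <- bias_correct(ph$volume)
  cov_of <- function(v) {
    B <- average_baseline(v)
    sd(B) / mean(B)
  }
  expect_gt(cov_of(ph$volume) / cov_of(bc2$volume), 10)
  # field is a function of the baseline alone: altering post-baseline
  # frames (enhancement) leaves it untouched
  arr <- ph$volume$data
  arr[, , , 10] <- arr[, , , 10] * 2
  vol2 <- volume4d(arr, ph$volume$voxel_size, ph$volume$frame_times,
                   ph$volume$n_baseline)
  expect_identical(bias_correct(vol2)$field, bc2$field)
})

test_that("Gaussian smoothing has the stated kernel width and conserves means", {
  ph <- generate_dce_phantom(demo_phantom_spec())
  # fwhm = 0 is the identity
  expect_identical(smooth_series(ph$volume, 0)$data, ph$volume$data)
  sm <- smooth_series(ph$volume, 0.1)
  # interior mean preserved within 0.1 %
  core <- sm$data[8:24, 8:24, 8:24, 1]
  core0 <- ph$volume$data[8:24, 8:24, 8:24, 1]
  expect_lt(abs(mean(core) - mean(core0)) / mean(core0), 1e-3)
  # impulse response: empirical half-maximum width matches the request
  d <- c(33, 33, 33)
  arr <- array(0, dim = c(d, 2)); arr[17, 17, 17, ] <- 1
  vol <- volume4d(arr, c(1, 1, 1), c(0, 1), 1)
  smv <- smooth_series(vol, fwhm_mm = 3)
  prof <- smv$data[, 17, 17, 1]
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  # linear interpolation at the half crossings
  lo <- above[1] - (prof[above[1]] - half) /
    (prof[above[1]] - prof[above[1] - 1])
  hi <- above[2] + (prof[above[2]] - half) /
    (prof[above[2]] - prof[above[2] + 1])
  expect_equal(hi - lo, 3, tolerance = 0.1)
})

test_that("nonconformant stage orders are flagged", {
  expect_silent(check_pipeline_order(c("register", "bias_correct", "smooth",
                                       "extract")))
  expect_silent(check_pipeline_order(c("register", "smooth")))
  expect_warning(check_pipeline_order(c("smooth", "register")),
                 "nonconformant")
})
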