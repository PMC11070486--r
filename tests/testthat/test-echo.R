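test_that("interface detection locates hand-placed pulses to sub-sample accuracy", {
  rec <- toy_recording(c(10.0, 13.7))
  ifc <- detect_interfaces(rec)
  half_wavelength <- 1540 / (2 * 40e6) * 1e3  # mm, at the RF sampling rate
  expect_true(ifc$accepted)
  expect_equal(ifc$z1_mm, 10.0, tolerance = half_wavelength)
  expect_equal(ifc$z2_mm, 13.7, tolerance = half_wavelength)
  expect_true(ifc$confidence > 0 && ifc$confidence <= 1)
})

test_that("peak depths are invariant to amplitude scaling", {
  a <- detect_interfaces(toy_recording(c(10.0, 13.7)))
  b <- detect_interfaces(toy_recording(c(10.0, 13.7), amp_scale = 10))
  expect_equal(a$z1_mm, b$z1_mm, tolerance = 1e-9)
  expect_equal(a$z2_mm, b$z2_mm, tolerance = 1e-9)
})

test_that("single-pulse frames are rejected, and excess rejection fails the recording", {
  cfg <- acquisition_config()
  good <- toy_recording(c(10.0, 13.7), n_frames = 9, cfg = cfg)
  lone <- toy_recording(10.0, cfg = cfg)
  rec <- good
  rec$frames$times <- 0:9
  rec$frames$amplitude <- cbind(good$frames$amplitude,
                                lone$frames$amplitude)
  ifc <- detect_interfaces(rec)
  expect_equal(sum(ifc$accepted), 9)
  expect_false(ifc$accepted[10])
  ## a recording that is mostly single-pulse frames is rejected outright
  expect_error(detect_interfaces(toy_recording(10.0, n_frames = 5)),
               "recording rejected")
})

test_that("thickness is the echo separation and skips rejected frames", {
  rec <- toy_recording(c(10.0, 13.7), n_frames = 4)
  ifc <- detect_interfaces(rec)
  ifc$accepted[2] <- FALSE
  ser <- thickness_series(ifc)
  expect_equal(nrow(ser), 3)
  expect_equal(ser$thickness_mm, rep(3.7, 3), tolerance = 1e-3)

  ifc_bad <- ifc
  ifc_bad$z2_mm <- ifc_bad$z1_mm
  expect_error(thickness_series(ifc_bad), "z2 <= z1")
  ifc_none <- ifc
  ifc_none$accepted[] <- FALSE
  expect_error(thickness_series(ifc_none), "all frames rejected")
})

test_that("initial thickness is the mean over the first contact episode", {
  ser <- structure(data.frame(time_s = 0:9,
                              thickness_mm = c(rep(4, 5), 4 - (1:5) * 0.2)),
                   class = c("thickness_series", "data.frame"))
  ## preload ramp 0 -> 0.45 N over the first 5 s, then loading above 0.5 N
  ft <- 0:9
  fN <- c(0.05, 0.15, 0.30, 0.45, 0.05, 1, 2, 3, 4, 5)
  expect_equal(initial_thickness(ser, ft, fN), 4)
  ## force never below the preload ceiling: no window
  expect_error(initial_thickness(ser, ft, rep(5, 10)), "no preload window")
  ## force never reaching contact: no window either
  expect_error(initial_thickness(ser, ft, rep(0.01, 10)), "no preload window")
})

test_that("synchronization interpolates the force channel onto frame times", {
  ser <- structure(data.frame(time_s = seq(0, 10, by = 0.5),
                              thickness_mm = rep(4, 21)),
                   class = c("thickness_series", "data.frame"))
  ## constant force: every sample carries it
  cv <- synchronize(ser, 0:10, rep(2, 11), h0 = 4)
  expect_true(all(cv$force_N == 2))
  ## linear ramp: interpolation is exact at any frame time
  cv2 <- synchronize(ser, 0:10, 0:10 * 0.3, h0 = 4)
  expect_equal(cv2$force_N, ser$time_s * 0.3, tolerance = 1e-12)
  ## non-monotonic stamps are rejected
  bad <- ser; bad$time_s[3] <- bad$time_s[2]
  expect_error(synchronize(bad, 0:10, rep(2, 11), h0 = 4),
               "strictly increasing")
})

test_that("full echo chain yields five labelled cycles and monotone loading", {
  traj <- simulate_indentation(linear_truth())
  rec <- render_recording(traj)
  ifc <- detect_interfaces(rec)
  ser <- thickness_series(ifc)
  h0 <- initial_thickness(ser, rec$force$times, rec$force$force_N)
  cv <- synchronize(ser, rec$force$times, rec$force$force_N, h0 = h0)
  expect_equal(max(cv$cycle, na.rm = TRUE), 5)
  ## curve carries exactly the accepted frames inside the force support
  expect_equal(nrow(cv), sum(ifc$accepted))
  ## noise-free loading ramps are non-decreasing after median filtering
  seg <- which(cv$cycle == 2)
  up <- seg[seq_len(which.max(cv$w_mm[seg]))]
  w_f <- stats::runmed(cv$w_mm[up], 5)
  expect_true(all(diff(w_f) >= -1e-9))
})
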