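test_that("default cohort reproduces the three-arm design of the study", {
  coh <- make_cohort(cohort_spec(seed = 42))
  expect_length(coh, 36)
  groups <- vapply(coh, function(s) s$group, 0)
  expect_equal(as.vector(table(factor(groups, levels = c(-145, -125, -105)))),
               c(12, 13, 11))
  for (s in coh) {
    expect_gt(s$pre$h0, 0)
    expect_gt(s$pre$toe_modulus, 0)
    expect_gte(s$pre$stiffening_rate, 0)
  }
})

test_that("identity effects with zero spread leave the post truth unchanged", {
  sp <- cohort_spec(n = c(2, 2, 2),
                    pre_thickness_sd = c(0, 0, 0),
                    thickness_ratio_mean = c(1, 1, 1),
                    thickness_ratio_sd = c(0, 0, 0),
                    e1_pre_cv = c(0, 0, 0), stiffening_cv = c(0, 0, 0),
                    modulus_effect = matrix(1, 3, 3),
                    modulus_effect_cv = matrix(0, 3, 3), seed = 1)
  coh <- make_cohort(sp)
  for (s in coh) {
    expect_equal(s$post$h0, s$pre$h0, tolerance = 1e-12)
    expect_equal(unname(truth_regional_moduli(s$post)),
                 unname(truth_regional_moduli(s$pre)), tolerance = 1e-12)
  }
})

test_that("cohorts are bit-reproducible under the master seed", {
  a <- make_cohort(cohort_spec(seed = 7))
  b <- make_cohort(cohort_spec(seed = 7))
  c <- make_cohort(cohort_spec(seed = 8))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("arm-level thickness ratios calibrate to the configured means", {
  sp <- cohort_spec(n = c(150, 2, 2), seed = 31)
  coh <- make_cohort(sp)
  r <- vapply(Filter(function(s) s$group == -105, coh),
              function(s) s$truth_ratios[["thickness"]], 0)
  expect_equal(mean(r), 0.745, tolerance = 0.03)
})

test_that("inter-region effect correlation is recovered from the truth ratios", {
  sp <- null_cohort_spec(retest_cv = 0.2, n = c(500, 2, 2), rho = 0.9,
                         seed = 12)
  coh <- make_cohort(sp)
  m <- t(vapply(Filter(function(s) s$group == -105, coh),
                function(s) s$truth_ratios[c("E1", "E2", "E3")], numeric(3)))
  rs <- c(cor(m[, 1], m[, 2]), cor(m[, 1], m[, 3]), cor(m[, 2], m[, 3]))
  expect_equal(mean(rs), 0.9, tolerance = 0.05)
})

test_that("simulated protocol delivers five loading cycles at 20% indentation", {
  traj <- simulate_indentation(linear_truth())
  curve <- curve_from_trajectory(traj)
  expect_equal(max(curve$cycle, na.rm = TRUE), 5)
  expect_equal(max(traj$w_mm) / 3.7, 0.20, tolerance = 0.01)
  expect_true(all(traj$force_N >= 0))
})

test_that("linear-elastic simulation matches the punch relation exactly", {
  tr <- linear_truth(E0 = 60)
  traj <- simulate_indentation(tr, h_convention = "initial")
  sel <- traj$w_mm > 0
  stiff <- traj$force_N[sel] / (traj$w_mm[sel] * 1e-3)
  expected <- 2 * 0.0045 * hayes_kappa(4.5 / 3.7, 0.45) * 60000 /
    (1 - 0.45^2)
  expect_equal(max(abs(stiff - expected)) / expected, 0, tolerance = 1e-9)
})

test_that("stiffening produces rising chord stiffness along the loading ramp", {
  traj <- simulate_indentation(jshape_truth(gamma = 4))
  h0 <- attr(traj, "h0_mm")
  chord <- function(eps) {
    i <- which(abs(traj$w_mm / h0 - eps) < 0.002 & traj$force_N > 0)
    mean(traj$force_N[i] / traj$w_mm[i])
  }
  expect_gt(chord(0.15), chord(0.05))
})

test_that("rendered channel lengths follow duration times sampling rate", {
  tr <- linear_truth()
  pr <- loading_protocol(preload_duration = 0)
  traj <- simulate_indentation(tr, pr)
  rec <- render_recording(traj)
  expect_length(rec$frames$times, 900)   # 40 s at 22.5 Hz
  expect_length(rec$force$force_N, 4000) # 40 s at 100 Hz
  expect_true(all(rec$force$force_N >= 0 & rec$force$force_N <= 49))
})

test_that("the infinite-SNR render is the noise-free limit", {
  traj <- simulate_indentation(linear_truth())
  a <- render_recording(traj, acquisition_config(echo_snr = Inf))
  b <- render_recording(traj, acquisition_config(echo_snr = Inf, seed = 99))
  expect_identical(a$frames$amplitude, b$frames$amplitude)
  ## ludicrously high finite SNR with a zero-noise force sensor is
  ## sample-for-sample equal to the noise-free render
  d <- render_recording(traj, acquisition_config(echo_snr = 1e6,
                                                 force_noise_sd = 0))
  expect_equal(d$frames$amplitude, a$frames$amplitude, tolerance = 1e-12)
})

test_that("echo overlap is flagged when the pulse cannot resolve the layer", {
  traj <- simulate_indentation(linear_truth(h0 = 3.7))
  cfg <- acquisition_config(pulse_sigma = 2)  # 1.54 mm envelope sigma
  expect_warning(rec <- render_recording(traj, cfg), "echo overlap")
  expect_true(rec$overlap_flagged)
})

test_that("renders are deterministic under the acquisition seed", {
  traj <- simulate_indentation(linear_truth(noise_scale = 1))
  a <- render_recording(traj, acquisition_config(echo_snr = 20, seed = 5))
  b <- render_recording(traj, acquisition_config(echo_snr = 20, seed = 5))
  c <- render_recording(traj, acquisition_config(echo_snr = 20, seed = 6))
  expect_identical(a, b)
  expect_false(identical(a$frames$amplitude, c$frames$amplitude))
})
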