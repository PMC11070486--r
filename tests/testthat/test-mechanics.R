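test_that("linear-elastic subjects give equal regional moduli at the truth", {
  res <- analyze_subject(linear_truth(E0 = 60), mode = "fast")
  for (E in c(res$triplet$E1, res$triplet$E2, res$triplet$E3))
    expect_equal(E, 60, tolerance = 0.02)
})

test_that("a J-shaped law orders the regional moduli E1 < E2 < E3", {
  res <- analyze_subject(jshape_truth(gamma = 4), mode = "fast")
  expect_lt(res$triplet$E1, res$triplet$E2)
  expect_lt(res$triplet$E2, res$triplet$E3)
  ## and the recovered values track the truth at each strain level
  tru <- truth_regional_moduli(jshape_truth(gamma = 4))
  expect_equal(res$triplet$E1, tru[["E1"]], tolerance = 0.03)
  expect_equal(res$triplet$E3, tru[["E3"]], tolerance = 0.03)
})

test_that("curves truncated below the linear region are refused", {
  pr <- loading_protocol(indent_fraction = 0.12)
  traj <- simulate_indentation(linear_truth(), pr)
  cv <- curve_from_trajectory(traj)
  expect_error(regional_moduli(cv), "insufficient strain")
})

test_that("cycle policy discards preconditioning and averages the rest", {
  traj <- simulate_indentation(linear_truth(E0 = 80))
  cv <- curve_from_trajectory(traj)
  expect_equal(cycle_policy(cv), 2:5)
  ## identical cycles: average equals any single cycle
  t_all <- regional_moduli(cv)
  t_one <- regional_moduli(cv, cycles = 3)
  expect_equal(t_all$E2, t_one$E2, tolerance = 1e-9)
})

test_that("with drifting cycles the triplet is the mean of per-cycle triplets", {
  traj <- simulate_indentation(linear_truth(E0 = 50))
  cv <- curve_from_trajectory(traj)
  drift <- 1 + 0.05 * ifelse(is.na(cv$cycle), 0, cv$cycle)
  cv$force_N <- cv$force_N * drift
  t_all <- regional_moduli(cv)
  per <- vapply(2:5, function(k) regional_moduli(cv, cycles = k)$E3, 0)
  expect_equal(t_all$E3, mean(per), tolerance = 1e-9)
})

test_that("single-cycle curves are analysed verbatim with a warning", {
  pr <- loading_protocol(n_cycles = 1, cycle_period = 8, total_duration = 8)
  traj <- simulate_indentation(linear_truth(E0 = 70), pr)
  cv <- curve_from_trajectory(traj)
  expect_warning(tr <- regional_moduli(cv), "single-cycle")
  expect_equal(tr$E1, 70, tolerance = 0.02)
})

test_that("noise-free parameter recovery holds across the physiological range", {
  set.seed(404)
  n <- 60
  h0s <- runif(n, 2, 6)
  E0s <- runif(n, 20, 200)
  errs <- vapply(seq_len(n), function(i) {
    res <- analyze_subject(linear_truth(h0 = h0s[i], E0 = E0s[i]),
                           mode = "fast")
    abs(res$triplet$E1 - E0s[i]) / E0s[i]
  }, 0)
  expect_lt(max(errs), 0.02)
})
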