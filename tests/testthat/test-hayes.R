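test_that("kappa has the exact half-space limit and monotone layer stiffening", {
  for (nu in c(0.30, 0.35, 0.40, 0.45, 0.50))
    expect_identical(hayes_kappa(0, nu), 1)

  ah <- seq(0, 10, by = 0.013)  # deliberately off-grid points
  k <- hayes_kappa(ah, 0.45)
  expect_true(all(k >= 1))
  expect_true(all(diff(k) >= 0))
  expect_gt(hayes_kappa(2.0, 0.45), hayes_kappa(0.5, 0.45))
  ## incompressible material stiffens fastest
  expect_gt(hayes_kappa(2, 0.50), hayes_kappa(2, 0.30))
})

test_that("interpolated kappa matches the independent Galerkin oracle", {
  for (pt in list(c(1.0, 0.45), c(0.5, 0.30), c(2.37, 0.50))) {
    expect_equal(hayes_kappa(pt[1], pt[2]), kappa_oracle(pt[1], pt[2]),
                 tolerance = 0.01)
  }
})

test_that("kappa refuses extrapolation and out-of-table Poisson ratios", {
  expect_error(hayes_kappa(10.5, 0.45), "outside the embedded kappa table")
  expect_error(hayes_kappa(-0.1, 0.45), ">= 0")
  expect_error(hayes_kappa(1, 0.2), "outside the embedded kappa table")
  expect_error(hayes_kappa(1, 0.6), "0.5")
})

test_that("effective modulus reproduces the hand-evaluated punch relation", {
  ## P = 1 N, w = 1 mm, kappa -> 1 (very thick layer), a = 4.5 mm, nu = 0.45
  E_hand <- (1 - 0.45^2) / (2 * 0.0045) * (1 / 1e-3) / 1000  # 88.61 kPa
  ## h large enough that the layer correction is 1 to interpolation accuracy
  expect_equal(effective_modulus(1, 1, h = 1e7), E_hand, tolerance = 1e-5)
  expect_equal(E_hand, 88.611, tolerance = 1e-4)
})

test_that("effective modulus is linear in force and zero at zero force", {
  geom <- indenter_geometry()
  E1 <- effective_modulus(1, 0.5, 3.5, geom)
  E2 <- effective_modulus(2, 0.5, 3.5, geom)
  expect_equal(E2, 2 * E1, tolerance = 1e-12)
  expect_identical(effective_modulus(0, 0.5, 3.5, geom), 0)
})

test_that("effective modulus rejects unphysical samples", {
  expect_error(effective_modulus(1, 0, 3.5), "w = 0")
  expect_error(effective_modulus(-1, 0.5, 3.5), ">= 0")
  expect_error(effective_modulus(1, 0.5, 0), "> 0")
})

test_that("modulus is invariant under the internal unit bookkeeping", {
  ## same physical sample expressed through different h used only in kappa:
  ## scaling a and h together leaves a/h (hence kappa) unchanged, and the
  ## prefactor scales as 1/a
  g1 <- indenter_geometry(a = 4.5)
  g2 <- indenter_geometry(a = 9.0)
  E1 <- effective_modulus(1, 0.5, 3.0, g1)
  E2 <- effective_modulus(1, 0.5, 6.0, g2)
  expect_equal(E1, 2 * E2, tolerance = 1e-12)
})
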