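test_that("paired t-test matches the textbook hand computation", {
  out <- paired_test(c(1, 2, 3), c(1, 3, 5))  # differences 0, 1, 2
  expect_equal(out$t, sqrt(3), tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$p, 2 * pt(-sqrt(3), 2), tolerance = 1e-12)
})

test_that("degenerate and antisymmetric paired cases follow the conventions", {
  same <- paired_test(c(4, 4, 7), c(4, 4, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  a <- paired_test(c(1, 2, 3), c(2, 4, 3))
  b <- paired_test(c(2, 4, 3), c(1, 2, 3))
  expect_equal(a$t, -b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_error(paired_test(1:3, 1:4), "equal length")
  expect_error(paired_test(1, 2), "at least 2")
})

test_that("ANOVA F, p and LSD agree with the sum-of-squares oracle", {
  ## hand-checkable toy: groups [1,2], [3,4], [5,6] -> F = 16
  toy <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  out <- oneway_anova_lsd(toy)
  expect_equal(out$F, 16, tolerance = 1e-12)
  expect_equal(out$p, pf(16, 2, 3, lower.tail = FALSE), tolerance = 1e-12)
  orc <- anova_oracle(toy)
  expect_equal(out$lsd$p, unname(orc$lsd_p), tolerance = 1e-12)
})

test_that("identical group means give F = 0 and two groups give F = t^2", {
  out <- oneway_anova_lsd(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3),
                               g3 = c(1, 2, 3)))
  expect_equal(out$F, 0)
  expect_equal(out$p, 1)

  set.seed(8)
  x <- rnorm(9); y <- rnorm(11, 0.5)
  two <- oneway_anova_lsd(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(two$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(two$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA guards its degenerate inputs", {
  expect_error(oneway_anova_lsd(list(a = c(1, 2))), "at least 2 groups")
  expect_error(oneway_anova_lsd(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(oneway_anova_lsd(list(a = c(2, 2), b = c(2, 2))),
               "zero total variance")
})

test_that("Pearson correlations reproduce exact and hand-computed cases", {
  x <- c(0.5, 1, 2, 9)
  pm <- pearson_matrix(data.frame(x = x, lin = 2 * x + 1, neg = -x))
  expect_equal(pm$r["x", "lin"], 1, tolerance = 1e-12)
  expect_equal(pm$r["x", "neg"], -1, tolerance = 1e-12)
  expect_true(isSymmetric(pm$r))
  expect_equal(diag(pm$r), c(x = 1, lin = 1, neg = 1))

  ## the classic 4-point set with r = 0.8 exactly
  pm2 <- pearson_matrix(data.frame(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4)))
  expect_equal(pm2$r["a", "b"], 0.8, tolerance = 1e-12)

  flat <- pearson_matrix(data.frame(a = c(1, 2, 3), b = c(2, 2, 2)))
  expect_true(is.na(flat$r["a", "b"]))
  expect_error(pearson_matrix(data.frame(a = 1:2, b = 2:3)), "n >= 3")
})

test_that("t, F, r and p match the independent oracles to 1e-8 on random fixtures", {
  set.seed(2024)
  for (k in 1:50) {
    n <- sample(5:20, 1)
    pre <- rnorm(n, 50, 10); post <- pre + rnorm(n, 2, 5)
    got <- paired_test(pre, post)
    orc <- paired_t_oracle(pre, post)
    expect_equal(got$t, orc$t, tolerance = 1e-8)
    expect_equal(got$p, orc$p, tolerance = 1e-8)

    gs <- lapply(sample(3:9, 3, replace = TRUE),
                 function(m) rnorm(m, sample(0:2, 1)))
    names(gs) <- c("a", "b", "c")
    gota <- oneway_anova_lsd(gs)
    orca <- anova_oracle(gs)
    expect_equal(gota$F, orca$F, tolerance = 1e-8)
    expect_equal(gota$p, orca$p, tolerance = 1e-8)
    expect_equal(gota$lsd$p, unname(orca$lsd_p), tolerance = 1e-8)

    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    gotr <- pearson_matrix(data.frame(x = x, y = y))
    orcr <- pearson_oracle(x, y)
    expect_equal(gotr$r["x", "y"], orcr$r, tolerance = 1e-8)
    expect_equal(gotr$p["x", "y"], orcr$p, tolerance = 1e-8)
  }
})

test_that("percentage ratios follow the definition and exclusion rule", {
  pre <- c(thickness = 4, E1 = 50)
  expect_equal(unname(ratio_percent(pre, c(thickness = 3, E1 = 50))),
               c(75, 100))
  expect_message(
    out <- ratio_percent(c(thickness = 0, E1 = 50),
                         c(thickness = 3, E1 = 60)),
    "pre <= 0")
  expect_true(is.na(out[["thickness"]]))
  expect_error(ratio_percent(c(a = 1), c(b = 2)), "identical measure names")
})
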