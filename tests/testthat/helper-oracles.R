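## Independent numerical oracles used to validate the package's
## implementations. These deliberately share no code with R/.

## ---- contact-mechanics oracle -------------------------------------------
## kappa(a/h, nu) for a rigid flat cylindrical punch on an elastic layer
## bonded to a rigid base, solved by a Ritz-Galerkin expansion of the
## contact pressure p(r) = sum c_n (1 - r^2)^(n - 1/2) (edge-singular punch
## basis), with the half-space part of the stiffness matrix in closed form
## (Weber-Schafheitlin) and the finite-layer correction by quadrature.
## This is a different formulation from the Fredholm dual-integral-equation
## route used to build the package's embedded grid.

oracle_gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = (b - a) / 2 * e$values + (a + b) / 2,
       w = (b - a) * e$vectors[1, ]^2)
}

oracle_layer_kernel <- function(x, nu) {
  k <- 3 - 4 * nu
  out <- (2 * k * sinh(2 * x) - 4 * x) /
    (2 * k * cosh(2 * x) + 1 + k^2 + 4 * x^2)
  out[x > 200] <- 1
  out
}

kappa_oracle <- function(alpha, nu, N = 8) {
  if (alpha == 0) return(1)
  m <- 0:(N - 1)
  WS <- outer(m, m, function(mm, nn) {
    2^(mm - 1/2) * gamma(mm + 1/2) * 2^(nn - 1/2) * gamma(nn + 1/2) *
      gamma(mm + nn + 1) * sqrt(pi) /
      (2^(mm + nn + 1) * gamma(nn + 1) * gamma(mm + 1) *
         gamma(mm + nn + 3/2))
  })
  g <- oracle_gauss_legendre(2000, 1e-9, 20 * alpha + 60)
  phit <- sapply(m, function(n)
    2^(n - 1/2) * gamma(n + 1/2) * g$x^(-(n + 1/2)) *
      besselJ(g$x, n + 1/2))
  fvals <- (oracle_layer_kernel(g$x / alpha, nu) - 1) * g$w
  A <- WS + t(phit) %*% (phit * fvals)
  b <- 1 / (2 * (1 - nu^2) * (2 * m + 1))
  cc <- solve(A, b)
  pi * (1 - nu^2) * sum(cc / (2 * m + 1))
}

## ---- textbook statistics oracles ----------------------------------------

paired_t_oracle <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

anova_oracle <- function(groups) {
  y <- unlist(groups)
  ns <- vapply(groups, length, 0L)
  means <- vapply(groups, mean, 0)
  grand <- mean(y)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  Fv <- (ssb / df1) / (ssw / df2)
  mse <- ssw / df2
  pairs <- combn(length(groups), 2)
  lsd_p <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    tv <- (means[i] - means[j]) / sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    2 * pt(-abs(tv), df2)
  })
  list(F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE), mse = mse,
       lsd_p = lsd_p)
}

pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}
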