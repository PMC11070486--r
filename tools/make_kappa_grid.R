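## Regenerates R/kappa-grid.R: kappa(a/h, nu) for a rigid frictionless
## cylindrical punch on an elastic layer bonded to a rigid base, solved from
## the dual-integral-equation formulation (Fredholm second kind, Nystrom).
## Run from the repository root: Rscript tools/make_kappa_grid.R

phi_layer <- function(x, nu) {
  k <- 3 - 4*nu
  out <- (2*k*sinh(2*x) - 4*x) / (2*k*cosh(2*x) + 1 + k^2 + 4*x^2)
  out[x > 200] <- 1
  out
}
gauss_legendre <- function(n, a, b) {
  i <- seq_len(n-1); beta <- i/sqrt(4*i^2 - 1)
  J <- matrix(0, n, n); J[cbind(i, i+1)] <- beta; J[cbind(i+1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = (b-a)/2*e$values + (a+b)/2, w = (b-a)*e$vectors[1, ]^2)
}
make_lambda <- function(nu, xmax = 30, nq = 1600) {
  g <- gauss_legendre(nq, 0, xmax)
  f <- (phi_layer(g$x, nu) - 1) * g$w
  function(v) drop(cos(outer(v, g$x)) %*% f)
}
## x_i +/- x_j on a uniform [0,1] grid take only 2n-1 values each
kappa_solve_raw <- function(alpha, nu, n = 241, lambda = make_lambda(nu)) {
  if (alpha == 0) return(1)
  x <- seq(0, 1, length.out = n); h <- x[2] - x[1]
  w <- rep(c(2, 4), length.out = n); w[1] <- 1; w[n] <- 1; w <- w*h/3
  lam_d <- lambda(alpha*h*abs(seq(-(n-1), n-1)))      # x_i - x_j
  lam_s <- lambda(alpha*h*seq(0, 2*(n-1)))            # x_i + x_j
  i <- rep(seq_len(n), times = n); j <- rep(seq_len(n), each = n)
  D <- lam_d[i - j + n] + lam_s[i + j - 1]
  K <- matrix(D, n, n) * rep(w, each = n) * alpha/pi
  sum(w * solve(diag(n) + K, rep(1, n)))
}

nu_grid <- seq(0.30, 0.50, by = 0.05)
ah_grid <- seq(0, 10, by = 0.05)
tab <- sapply(nu_grid, function(nu) {
  lam <- make_lambda(nu)
  vapply(ah_grid, kappa_solve_raw, 0, nu = nu, lambda = lam)
})
dimnames(tab) <- list(NULL, sprintf("nu_%.2f", nu_grid))

con <- file("R/kappa-grid.R", "w")
writeLines(c(
  "## Generated by tools/make_kappa_grid.R -- do not edit by hand.",
  "## kappa(a/h, nu) grid for the bonded-layer flat-punch correction factor.",
  "",
  ".kappa_ah_grid <- seq(0, 10, by = 0.05)",
  ".kappa_nu_grid <- seq(0.30, 0.50, by = 0.05)",
  "",
  ".kappa_grid <- matrix(c("), con)
vals <- apply(tab, 2, function(col) paste(sprintf("%.8f", col), collapse = ", "))
writeLines(paste0("  ", paste(vals, collapse = ",\n  "), collapse = ""), con)
writeLines(sprintf("), nrow = %d, ncol = %d)", length(ah_grid), length(nu_grid)), con)
close(con)
cat("wrote R/kappa-grid.R\n")
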