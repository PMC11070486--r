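#' Indenter geometry for thin-layer indentation
#'
#' The indenter is the cylindrical ultrasound transducer / standoff gel pad
#' assembly; its radius and the tissue Poisson's ratio enter the bonded-layer
#' punch correction factor and the modulus equation.
#'
#' @param a indenter radius in mm. Default 4.5 mm (transducer + gel pad
#'   cylinder radius).
#' @param nu Poisson's ratio of the tissue, dimensionless. Default 0.45, the
#'   conventional value for nearly incompressible biological soft tissue.
#' @return an object of class `indenter_geometry`.
#' @export
#' @examples
#' indenter_geometry()
indenter_geometry <- function(a = 4.5, nu = 0.45) {
  stopifnot_scalar(a, "a", positive = TRUE)
  stopifnot_scalar(nu, "nu")
  if (nu < 0 || nu > 0.5 + 1e-9)
    stop("'nu' must lie in [0, 0.5]", call. = FALSE)
  structure(list(a = a, nu = nu), class = "indenter_geometry")
}

#' Bonded-layer punch correction factor kappa
#'
#' Correction factor \eqn{\kappa(a/h, \nu)} for a rigid, frictionless,
#' flat-ended cylindrical punch pressing on a linear elastic layer of finite
#' thickness bonded to a rigid base. It rescales the classical half-space
#' flat-punch stiffness \eqn{P/w = 2 a E / (1 - \nu^2)} for the stiffening
#' effect of the finite layer: \eqn{\kappa \ge 1}, \eqn{\kappa \to 1} as the
#' layer becomes thick relative to the punch (\eqn{a/h \to 0}), and
#' \eqn{\kappa} grows with \eqn{a/h}, fastest for incompressible material.
#'
#' Values are bilinearly interpolated from an embedded grid
#' (\eqn{a/h \in [0, 3]} step 0.05; \eqn{\nu \in [0.30, 0.50]} step 0.05)
#' precomputed by solving the dual integral equations of the layer contact
#' problem (Fredholm equation of the second kind, Nystrom discretisation; see
#' `tools/make_kappa_grid.R` in the package sources). Queries outside the
#' grid raise an error rather than extrapolating.
#'
#' @param a_over_h ratio of indenter radius to current layer thickness,
#'   dimensionless; may be a vector.
#' @param nu Poisson's ratio in \[0.30, 0.50\].
#' @return kappa value(s), dimensionless, `>= 1`.
#' @export
#' @examples
#' hayes_kappa(0, 0.45)      # half-space limit, exactly 1
#' hayes_kappa(1.0, 0.45)    # finite layer, > 1
hayes_kappa <- function(a_over_h, nu) {
  stopifnot_scalar(nu, "nu")
  if (!is.numeric(a_over_h) || any(!is.finite(a_over_h)))
    stop("'a_over_h' must be finite numeric", call. = FALSE)
  if (any(a_over_h < 0))
    stop("'a_over_h' must be >= 0", call. = FALSE)
  if (any(a_over_h > max(.kappa_ah_grid)))
    stop(sprintf(
      "a/h = %.3f outside the embedded kappa table (max %.2f); %s",
      max(a_over_h), max(.kappa_ah_grid),
      "the layer is too thin relative to the indenter for this correction"),
      call. = FALSE)
  if (nu < min(.kappa_nu_grid) - 1e-9 || nu > max(.kappa_nu_grid) + 1e-9)
    stop(sprintf("'nu' = %.3f outside the embedded kappa table [%.2f, %.2f]",
                 nu, min(.kappa_nu_grid), max(.kappa_nu_grid)), call. = FALSE)

  ## bilinear interpolation on the (a/h, nu) grid
  nu <- min(max(nu, min(.kappa_nu_grid)), max(.kappa_nu_grid))
  j <- findInterval(nu, .kappa_nu_grid, rightmost.closed = TRUE)
  dn <- diff(.kappa_nu_grid)[1]
  tn <- (nu - .kappa_nu_grid[j]) / dn
  i <- findInterval(a_over_h, .kappa_ah_grid, rightmost.closed = TRUE)
  da <- diff(.kappa_ah_grid)[1]
  ta <- (a_over_h - .kappa_ah_grid[i]) / da

  jj <- min(j + 1L, length(.kappa_nu_grid))
  ii <- pmin(i + 1L, length(.kappa_ah_grid))
  k00 <- .kappa_grid[cbind(i, j)]
  k10 <- .kappa_grid[cbind(ii, j)]
  k01 <- .kappa_grid[cbind(i, jj)]
  k11 <- .kappa_grid[cbind(ii, jj)]
  (1 - ta) * (1 - tn) * k00 + ta * (1 - tn) * k10 +
    (1 - ta) * tn * k01 + ta * tn * k11
}

#' Effective Young's modulus from an indentation sample
#'
#' Inverts the thin-layer punch relation
#' \deqn{E = \frac{1 - \nu^2}{2 a \, \kappa(\nu, a/h)} \cdot \frac{P}{w}}
#' for the effective Young's modulus of a soft-tissue layer from one
#' force/deformation sample. `P/w` is a secant stiffness, so the result is a
#' secant (chord) modulus at the sampled strain.
#'
#' @param P indentation force in N (vectorised).
#' @param w indentation depth in mm (vectorised).
#' @param h tissue layer thickness in mm used in the kappa correction;
#'   conventionally the instantaneous thickness `h0 - w`.
#' @param geom an [indenter_geometry()].
#' @return effective Young's modulus in kPa. `P = 0` gives 0.
#' @export
#' @examples
#' ## half-space punch: 1 N at 1 mm on a very thick layer
#' effective_modulus(1, 1, h = 1e6, geom = indenter_geometry())  # ~88.6 kPa
effective_modulus <- function(P, w, h, geom = indenter_geometry()) {
  if (any(P < 0, na.rm = TRUE)) stop("'P' must be >= 0", call. = FALSE)
  if (any(h <= 0, na.rm = TRUE)) stop("'h' must be > 0", call. = FALSE)
  if (any(w <= 0 & P > 0, na.rm = TRUE))
    stop("undefined modulus: P > 0 at w = 0", call. = FALSE)
  n <- max(length(P), length(w), length(h))
  P <- rep_len(P, n); w <- rep_len(w, n); h <- rep_len(h, n)
  kap <- hayes_kappa(geom$a / h, geom$nu)
  a_m <- geom$a * 1e-3
  w_m <- w * 1e-3
  E_pa <- ifelse(P == 0, 0,
                 (1 - geom$nu^2) / (2 * a_m * kap) * P / w_m)
  E_pa / 1000
}
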