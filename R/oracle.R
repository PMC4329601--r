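#' Numerical mass-property oracle
#'
#' Computes mass, center of mass, and inertia tensor of a
#' [stadium_solid()] or [semiellipsoid()] by numerical integration over
#' the solid's volume, independently of the closed forms in
#' [solid_properties()]. The volume integral is evaluated as an iterated
#' integral: Gauss-Legendre quadrature along the longitudinal axis, and
#' within each cross-section a trigonometric substitution resolves the
#' boundary (for a stadium of radius r and thickness t, the half-width at
#' height y is `t + sqrt(r^2 - y^2)`; substituting `y = r sin(theta)`
#' makes the integrand smooth) followed by Gauss-Legendre in theta. The
#' error decreases as `resolution` grows.
#'
#' This routine exists to validate the analytic formulas; it shares no
#' code or algebra with them.
#'
#' @param s A `"stadium_solid"` or `"semiellipsoid"`.
#' @param resolution Number of quadrature nodes per direction.
#' @return A [rigid_body()] about the base center, in the solid-local
#'   frame.
#' @export
numeric_mass_properties <- function(s, resolution = 48) {
  stopifnot(resolution >= 2)
  gl <- gauss_legendre(resolution)
  if (inherits(s, "stadium_solid")) {
    h <- s$height; rho <- s$density
    u <- gl$x; wz <- gl$w * h        # z = h u, u in [0, 1]
    r <- s$bottom$r + (s$top$r - s$bottom$r) * u
    t <- s$bottom$t + (s$top$t - s$bottom$t) * u
    sec <- stadium_section_quadrature(r, t, gl)
  } else if (inherits(s, "semiellipsoid")) {
    h <- s$c; rho <- s$density
    u <- gl$x; wz <- gl$w * h
    scale <- sqrt(pmax(0, 1 - u^2))
    sec <- ellipse_section_quadrature(s$a * scale, s$b * scale, gl)
  } else stop("unsupported solid type", call. = FALSE)

  z <- h * u
  mass <- rho * sum(wz * sec$area)
  zbar <- rho * sum(wz * z * sec$area) / mass
  ixx <- rho * sum(wz * (sec$sy2 + sec$area * z^2))
  iyy <- rho * sum(wz * (sec$sx2 + sec$area * z^2))
  izz <- rho * sum(wz * (sec$sx2 + sec$sy2))
  rigid_body(mass, c(0, 0, zbar), diag(c(ixx, iyy, izz)), frame = "local")
}

# Gauss-Legendre nodes/weights on [0, 1] via the Golub-Welsch eigenvalue
# method (symmetric tridiagonal Jacobi matrix).
gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0.5, w = 1))
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  jac <- matrix(0, n, n)
  jac[cbind(k, k + 1)] <- beta
  jac[cbind(k + 1, k)] <- beta
  e <- eigen(jac, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = (x[ord] + 1) / 2, w = w[ord] / 2)  # mapped to [0, 1]
}

# Per-slice section integrals for stadium cross-sections at vectors of
# (r, t): area, int x^2 dA (sx2, wide axis), int y^2 dA (sy2, depth).
# Integration over y in [-r, r] with y = r sin(theta); the half-width is
# X(theta) = t + r cos(theta).
stadium_section_quadrature <- function(r, t, gl) {
  theta <- pi * (gl$x - 0.5)           # [-pi/2, pi/2]
  wt <- gl$w * pi
  cs <- cos(theta); sn <- sin(theta)
  area <- sx2 <- sy2 <- numeric(length(r))
  for (i in seq_along(r)) {
    xw <- t[i] + r[i] * cs             # half-width at y
    dy <- r[i] * cs                    # dy/dtheta
    area[i] <- sum(wt * 2 * xw * dy)
    sx2[i] <- sum(wt * (2 / 3) * xw^3 * dy)
    sy2[i] <- sum(wt * 2 * (r[i] * sn)^2 * xw * dy)
  }
  list(area = area, sx2 = sx2, sy2 = sy2)
}

# Same for elliptical sections with semi-axes (a, b): y = b sin(theta),
# half-width X = a cos(theta).
ellipse_section_quadrature <- function(a, b, gl) {
  theta <- pi * (gl$x - 0.5)
  wt <- gl$w * pi
  cs <- cos(theta); sn <- sin(theta)
  area <- sx2 <- sy2 <- numeric(length(a))
  for (i in seq_along(a)) {
    xw <- a[i] * cs
    dy <- b[i] * cs
    area[i] <- sum(wt * 2 * xw * dy)
    sx2[i] <- sum(wt * (2 / 3) * xw^3 * dy)
    sy2[i] <- sum(wt * 2 * (b[i] * sn)^2 * xw * dy)
  }
  list(area = area, sx2 = sx2, sy2 = sy2)
}
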