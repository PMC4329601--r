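#' Stadium solid
#'
#' A solid lofted between two parallel stadia a distance `height` apart,
#' with radius and thickness interpolated linearly in between. This is the
#' building block of every body segment except the cranium. The solid's
#' local frame has its origin at the center of the bottom stadium, z along
#' the longitudinal axis toward the top stadium, x along the stadium's
#' wide (mediolateral) axis, and y along its depth axis.
#'
#' @param bottom,top [stadium()] cross-sections. Both must share an
#'   orientation (circles are orientation-neutral).
#' @param height Longitudinal distance between the stadia (m, > 0).
#' @param density Uniform density (kg/m^3, > 0).
#' @param label Optional name.
#' @return Object of class `"stadium_solid"`.
#' @export
stadium_solid <- function(bottom, top, height, density, label = "") {
  stopifnot(inherits(bottom, "stadium"), inherits(top, "stadium"))
  if (!is.numeric(height) || height <= 0)
    stop(sprintf("stadium solid %s: height must be positive", label),
         call. = FALSE)
  if (!is.numeric(density) || density <= 0)
    stop(sprintf("stadium solid %s: density must be positive", label),
         call. = FALSE)
  if (!is_circle(bottom) && !is_circle(top) &&
      bottom$orientation != top$orientation)
    stop(sprintf("stadium solid %s: bounding stadia have mismatched orientations",
                 label), call. = FALSE)
  orientation <- if (!is_circle(bottom)) bottom$orientation
                 else top$orientation
  structure(list(bottom = bottom, top = top, height = height,
                 density = density, orientation = orientation,
                 label = label),
            class = "stadium_solid")
}

#' Semi-ellipsoid solid
#'
#' Half of a solid ellipsoid, flat face down: semi-axes `a` (x) and `b`
#' (y) span the base ellipse, and the apex sits at height `c` on the local
#' z-axis. Models the cranium above the ear level.
#'
#' @param a,b Base semi-axes (m, > 0).
#' @param c Height of the apex above the base plane (m, > 0).
#' @param density Uniform density (kg/m^3, > 0).
#' @param label Optional name.
#' @return Object of class `"semiellipsoid"`.
#' @export
semiellipsoid <- function(a, b, c, density, label = "") {
  vals <- c(a = a, b = b, c = c, density = density)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop(sprintf("semiellipsoid %s: a, b, c and density must be positive",
                 label), call. = FALSE)
  structure(list(a = a, b = b, c = c, density = density, label = label),
            class = "semiellipsoid")
}

# ---- exact polynomial machinery -------------------------------------------
# Cross-section properties of a stadium with radius r and thickness t
# (wide axis x, depth axis y):
#   area          A  = 4 r t + pi r^2
#   depth moment  Ix = int y^2 dA = (4/3) t r^3 + (pi/4) r^4
#   width moment  Iy = int x^2 dA = (4/3) r t^3 + (8/3) t r^3
#                                   + pi t^2 r^2 + (pi/4) r^4
# Along the solid, r(u) and t(u) are degree-1 polynomials in u = z/h, so
# every integrand below is a polynomial of degree <= 4 and is integrated
# exactly from its coefficients. No denominators appear, so circles
# (t = 0) need no special treatment here.

poly_mul <- function(a, b) {
  res <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    res[idx] <- res[idx] + a[i] * b
  }
  res
}

poly_int01 <- function(a) sum(a / seq_along(a))

stadium_section_polys <- function(r0, r1, t0, t1) {
  r <- c(r0, r1 - r0)
  t <- c(t0, t1 - t0)
  r2 <- poly_mul(r, r); r3 <- poly_mul(r2, r); r4 <- poly_mul(r2, r2)
  t2 <- poly_mul(t, t); t3 <- poly_mul(t2, t)
  area <- 4 * poly_mul(r, t)
  area[seq_along(r2)] <- area[seq_along(r2)] + pi * r2
  ix <- (4 / 3) * poly_mul(t, r3)
  ix[seq_along(r4)] <- ix[seq_along(r4)] + (pi / 4) * r4
  iy <- (4 / 3) * poly_mul(r, t3) + (8 / 3) * poly_mul(t, r3) +
    pi * poly_mul(t2, r2)
  iy[seq_along(r4)] <- iy[seq_along(r4)] + (pi / 4) * r4
  list(area = area, ix = ix, iy = iy)
}

# generic path: exact integration of the section polynomials
stadium_solid_properties_generic <- function(r0, r1, t0, t1, h, rho) {
  sp <- stadium_section_polys(r0, r1, t0, t1)
  a0 <- poly_int01(sp$area)            # int A du
  a1 <- poly_int01(c(0, sp$area))      # int u A du
  a2 <- poly_int01(c(0, 0, sp$area))   # int u^2 A du
  mass <- rho * h * a0
  zbar <- if (a0 > 0) h * a1 / a0 else h / 2
  ixs <- poly_int01(sp$ix)
  iys <- poly_int01(sp$iy)
  izz <- rho * h * (ixs + iys)
  ixx <- rho * (h * ixs + h^3 * a2)
  iyy <- rho * (h * iys + h^3 * a2)
  list(mass = mass, com = c(0, 0, zbar),
       inertia = diag(c(ixx, iyy, izz)))
}

# both bounding stadia are circles: classical truncated-cone closed forms
truncated_cone_properties <- function(r0, r1, h, rho) {
  s2 <- r0^2 + r0 * r1 + r1^2
  mass <- rho * pi * h * s2 / 3
  zbar <- h * (r0^2 + 2 * r0 * r1 + 3 * r1^2) / (4 * s2)
  s4 <- r0^4 + r0^3 * r1 + r0^2 * r1^2 + r0 * r1^3 + r1^4
  izz <- rho * pi * h * s4 / 10
  # int r^2 z^2 dz with r linear in z
  rz2 <- h^3 * (r0^2 / 3 + (r1 - r0) * r0 / 2 + (r1 - r0)^2 / 5)
  ixx <- rho * pi * (h * s4 / 20 + rz2)
  list(mass = mass, com = c(0, 0, zbar),
       inertia = diag(c(ixx, ixx, izz)))
}

# exactly one circle: evaluate the solid upside-down and transport back.
stadium_solid_properties_swapped <- function(s) {
  flipped <- stadium_solid(s$top, s$bottom, s$height, s$density, s$label)
  pf <- solid_properties_local(flipped, degenerate = FALSE)
  xf <- frame_transform(rot_x(pi), c(0, 0, s$height))
  shift_reference_point(transport_properties(pf, xf, frame = "local"),
                        c(0, 0, 0))
}

solid_properties_local <- function(s, degenerate = TRUE) {
  UseMethod("solid_properties_local")
}

#' @export
solid_properties_local.stadium_solid <- function(s, degenerate = TRUE) {
  b <- s$bottom; tp <- s$top
  if (degenerate && is_circle(b) && is_circle(tp)) {
    pr <- truncated_cone_properties(b$r, tp$r, s$height, s$density)
  } else if (degenerate && xor(is_circle(b), is_circle(tp))) {
    return(stadium_solid_properties_swapped(s))
  } else {
    pr <- stadium_solid_properties_generic(b$r, tp$r, b$t, tp$t,
                                           s$height, s$density)
  }
  rigid_body(pr$mass, pr$com, pr$inertia, frame = "local")
}

#' @export
solid_properties_local.semiellipsoid <- function(s, degenerate = TRUE) {
  mass <- s$density * (2 / 3) * pi * s$a * s$b * s$c
  com <- c(0, 0, 3 * s$c / 8)
  # about the base center: each squared-coordinate integral is mass/5 times
  # the corresponding squared semi-axis (the half-body shares the full
  # ellipsoid's ratios; the z-integral halves along with the mass)
  inertia <- diag(c(mass * (s$b^2 + s$c^2) / 5,
                    mass * (s$a^2 + s$c^2) / 5,
                    mass * (s$a^2 + s$b^2) / 5))
  rigid_body(mass, com, inertia, frame = "local")
}

#' Mass properties of a primitive solid
#'
#' Closed-form mass, center of mass, and inertia tensor of a
#' [stadium_solid()] or [semiellipsoid()], about the center of its base
#' cross-section, in the solid-local frame (z longitudinal, x along the
#' stadium's wide axis). Obtained by exact polynomial integration of the
#' cross-section's area and second moments along the axis; solids bounded
#' by one circle are evaluated through the swapped (upside-down)
#' arrangement and solids bounded by two circles through the classical
#' truncated-cone closed forms. No small-thickness approximation is used
#' anywhere.
#'
#' @param s A `"stadium_solid"` or `"semiellipsoid"`.
#' @return A [rigid_body()] in the solid-local frame, reference point at
#'   the base center.
#' @examples
#' cyl <- stadium_solid(stadium(r = 1, t = 0), stadium(r = 1, t = 0),
#'                      height = 2, density = 1)
#' solid_properties(cyl)   # mass 2*pi, I_zz = pi
#' @export
solid_properties <- function(s) solid_properties_local(s)
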