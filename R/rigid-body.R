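#' Rigid-body mass properties
#'
#' Container for the mass, center-of-mass position, and inertia tensor of a
#' rigid body. The tensor is expressed about a stated reference `point`
#' (not necessarily the center of mass) with axes of a stated `frame`.
#'
#' @param mass Mass in kg (>= 0).
#' @param com Center of mass, numeric length-3 (m), in `frame` coordinates.
#' @param inertia 3x3 symmetric inertia tensor (kg m^2) about `point`.
#' @param frame Identifier for the coordinate frame (free-form tag).
#' @param point Reference point of `inertia`, numeric length-3 (m).
#' @return Object of class `"rigid_body"`.
#' @export
rigid_body <- function(mass, com, inertia, frame = "local",
                       point = c(0, 0, 0)) {
  com <- as.numeric(com); point <- as.numeric(point)
  inertia <- unname(as.matrix(inertia))
  stopifnot(length(mass) == 1L, is.finite(mass), mass >= 0,
            length(com) == 3L, all(is.finite(com)),
            all(dim(inertia) == c(3L, 3L)), all(is.finite(inertia)),
            length(point) == 3L)
  if (max(abs(inertia - t(inertia))) > 1e-9 * max(1, max(abs(inertia))))
    stop("inertia tensor must be symmetric", call. = FALSE)
  inertia <- (inertia + t(inertia)) / 2
  structure(list(mass = mass, com = com, inertia = inertia,
                 frame = frame, point = point),
            class = "rigid_body")
}

#' @export
print.rigid_body <- function(x, ...) {
  cat(sprintf("rigid body: mass %.6g kg, frame '%s'\n", x$mass, x$frame))
  cat(sprintf("  com   = (%.6g, %.6g, %.6g) m\n", x$com[1], x$com[2], x$com[3]))
  cat(sprintf("  about = (%.6g, %.6g, %.6g) m\n", x$point[1], x$point[2], x$point[3]))
  cat("  inertia (kg m^2):\n")
  m <- format(x$inertia, digits = 6)
  for (i in 1:3) cat("   ", m[i, 1], m[i, 2], m[i, 3], "\n")
  invisible(x)
}

#' Rigid frame transform
#'
#' A proper rigid transform mapping coordinates in a body-local frame to a
#' parent frame: `x_parent = rotation %*% x_local + origin`.
#'
#' @param rotation 3x3 proper orthonormal matrix (columns are the local
#'   axes expressed in the parent frame).
#' @param origin Position of the local origin in the parent frame (m).
#' @return Object of class `"frame_transform"`.
#' @export
frame_transform <- function(rotation = diag(3), origin = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation)); origin <- as.numeric(origin)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(origin) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      det(rotation) < 0)
    stop("rotation must be proper orthonormal (R'R = I, det = +1)",
         call. = FALSE)
  structure(list(rotation = rotation, origin = origin),
            class = "frame_transform")
}

compose_transforms <- function(parent, child) {
  # parent o child: maps child-local coords all the way to parent's parent
  frame_transform(parent$rotation %*% child$rotation,
                  parent$origin + as.numeric(parent$rotation %*% child$origin))
}

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, used to build
#' body-fixed X-Y-Z Euler sequences.
#'
#' @param theta Angle in radians.
#' @return 3x3 rotation matrix.
#' @name rotations
NULL

#' @rdname rotations
#' @export
rot_x <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

#' @rdname rotations
#' @export
rot_y <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

#' @rdname rotations
#' @export
rot_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

# inertia increment for moving the reference point away from the COM:
# I_P = I_COM + m ((d.d) E - d d'), d = P - COM
parallel_axis_term <- function(mass, d) {
  d <- as.numeric(d)
  mass * (sum(d * d) * diag(3) - tcrossprod(d))
}

#' Shift the reference point of an inertia tensor
#'
#' Re-expresses the stored tensor about a new reference point in the same
#' frame, routing through the center of mass (parallel axis theorem applied
#' twice, valid between any two points).
#'
#' @param props A [rigid_body()] object.
#' @param point New reference point, length-3, same frame.
#' @return A `"rigid_body"` with `point` updated.
#' @export
shift_reference_point <- function(props, point) {
  stopifnot(inherits(props, "rigid_body"))
  point <- as.numeric(point)
  i_com <- props$inertia - parallel_axis_term(props$mass, props$point - props$com)
  inertia <- i_com + parallel_axis_term(props$mass, point - props$com)
  rigid_body(props$mass, props$com, inertia, props$frame, point)
}

#' Transport rigid-body properties to a new frame
#'
#' Applies a rigid transform to the stored properties: positions map as
#' `x -> R x + o`, the tensor as `I -> R I R'`. Mass and the tensor's
#' eigenvalues are unchanged by the rotation; the reference point moves
#' with the body (no parallel-axis shift is introduced, use
#' [shift_reference_point()] for that).
#'
#' @param props A [rigid_body()] object.
#' @param xf A [frame_transform()] mapping the current frame to the target.
#' @param frame Tag for the resulting frame.
#' @return A `"rigid_body"` expressed in the target frame.
#' @export
transport_properties <- function(props, xf, frame = "global") {
  stopifnot(inherits(props, "rigid_body"), inherits(xf, "frame_transform"))
  r <- xf$rotation
  rigid_body(props$mass,
             as.numeric(r %*% props$com) + xf$origin,
             r %*% props$inertia %*% t(r),
             frame,
             as.numeric(r %*% props$point) + xf$origin)
}

#' Combine rigid bodies
#'
#' Aggregates several bodies (already expressed in one common frame) into
#' one: masses add, the center of mass is the mass-weighted mean, and the
#' tensors are shifted to a common reference point and summed.
#'
#' @param bodies List of [rigid_body()] objects in the same frame.
#' @param point Reference point of the combined tensor; `"com"` (default)
#'   uses the combined center of mass, or give a length-3 point.
#' @return A `"rigid_body"` for the aggregate.
#' @export
combine_rigid_bodies <- function(bodies, point = "com") {
  stopifnot(length(bodies) >= 1L)
  frames <- vapply(bodies, function(b) b$frame, character(1))
  if (length(unique(frames)) != 1L)
    stop("all bodies must be expressed in the same frame", call. = FALSE)
  mass <- sum(vapply(bodies, function(b) b$mass, numeric(1)))
  com <- Reduce(`+`, lapply(bodies, function(b) b$mass * b$com))
  com <- if (mass > 0) com / mass else bodies[[1]]$com
  pt <- if (identical(point, "com")) com else as.numeric(point)
  inertia <- Reduce(`+`, lapply(bodies, function(b)
    shift_reference_point(b, pt)$inertia))
  rigid_body(mass, com, inertia, frames[1], pt)
}
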