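#' Build a personalised human model
#'
#' Assembles the full body model from a measurement set: 11 rigid
#' segments (pelvis `P`, thorax `T`, chest-head `C`, left/right upper arm
#' `A1`/`B1`, forearm-hand `A2`/`B2`, thigh `J1`/`K1`, shank-foot
#' `J2`/`K2`) composed of 40 solids over 45 stadium levels, on a
#' kinematic tree rooted at the pelvis. The global frame has its origin
#' at the bottom center of solid `s0` (the midpoint of the two hip joint
#' centers), z vertical (up along the pelvis), x mediolateral toward the
#' left hip, y posterior; with all 21 joint angles zero every segment's
#' local axes align with the global axes.
#'
#' If the measurement set carries a measured total mass (`totalmass` in
#' the measurement file) the solid densities are scaled so the model
#' total mass matches it.
#'
#' @param meas A `"measurement_set"` (see [read_measurements()]).
#' @param densities Per-solid density table; default [default_densities()].
#' @param symmetric Average left and right limb measurements first
#'   ([average_limbs()]); off by default.
#' @param configuration Named angles (radians) to pose the model with;
#'   omitted angles are zero.
#' @return Object of class `"human"`.
#' @export
human_model <- function(meas, densities = default_densities(),
                        symmetric = FALSE, configuration = NULL) {
  stopifnot(inherits(meas, "measurement_set"))
  if (symmetric) meas <- average_limbs(meas)
  densities <- check_densities(densities)
  stack <- resolve_levels(meas, densities)
  h <- structure(list(
    meas = meas,
    stack = stack,
    densities = densities,
    configuration = validate_configuration(configuration),
    local_props = lapply(stack$solids, solid_properties),
    kinematics = build_kinematics(stack)),
    class = "human")
  if (!is.null(meas$total_mass))
    h <- scale_human_by_mass(h, meas$total_mass)
  h
}

# Fixed (configuration-independent) kinematic data: per segment, the
# joint-center position in the parent frame, the stacking direction, and
# each solid's mounting transform in the segment frame.
build_kinematics <- function(stack) {
  pos <- stack$positions
  ls0 <- stack$levels$Ls0
  ls4 <- stack$levels$Ls4
  hip_x <- (ls0$t + ls0$r) / 2
  sh_x <- ls4$t + ls4$r

  seg <- function(parent, origin, direction, base_level)
    list(parent = parent, origin = origin, direction = direction,
         base_level = base_level)
  k <- list(
    P  = seg(NA, c(0, 0, 0), +1, "Ls0"),
    T  = seg("P", c(0, 0, pos[["Ls2"]]), +1, "Ls2"),
    C  = seg("T", c(0, 0, pos[["Ls3"]] - pos[["Ls2"]]), +1, "Ls3"),
    A1 = seg("C", c(sh_x, 0, pos[["Ls4"]] - pos[["Ls3"]]), -1, "La0"),
    A2 = seg("A1", c(0, 0, -pos[["La2"]]), -1, "La2"),
    B1 = seg("C", c(-sh_x, 0, pos[["Ls4"]] - pos[["Ls3"]]), -1, "Lb0"),
    B2 = seg("B1", c(0, 0, -pos[["Lb2"]]), -1, "Lb2"),
    J1 = seg("P", c(hip_x, 0, 0), -1, "Lj0"),
    J2 = seg("J1", c(0, 0, -pos[["Lj3"]]), -1, "Lj3"),
    K1 = seg("P", c(-hip_x, 0, 0), -1, "Lk0"),
    K2 = seg("K1", c(0, 0, -pos[["Lk3"]]), -1, "Lk3"))

  tab <- solid_table()
  for (s in names(stack$segments)) {
    solids <- stack$segments[[s]]
    mounts <- list()
    for (lab in solids) {
      bot <- tab$bottom[tab$solid == lab]
      zb <- k[[s]]$direction * (pos[[bot]] - pos[[k[[s]]$base_level]])
      rot <- diag(3)
      if (k[[s]]$direction < 0) rot <- rot_x(pi)
      obj <- stack$solids[[lab]]
      if (inherits(obj, "stadium_solid") && obj$orientation == "AP")
        rot <- rot %*% rot_z(pi / 2)
      mounts[[lab]] <- frame_transform(rot, c(0, 0, zb))
    }
    k[[s]]$mounts <- mounts
  }
  k
}

# Global frame transform of every segment under the current configuration.
segment_transforms <- function(h) {
  k <- h$kinematics
  xfs <- list()
  for (s in names(k)) {
    local <- frame_transform(segment_rotation(s, h$configuration),
                             k[[s]]$origin)
    xfs[[s]] <- if (is.na(k[[s]]$parent[1])) local
                else compose_transforms(xfs[[k[[s]]$parent]], local)
  }
  xfs
}

# All 40 solids' properties in the global frame (each about its own
# mounting point).
solid_global_properties <- function(h) {
  xfs <- segment_transforms(h)
  out <- list()
  for (s in names(h$kinematics)) {
    for (lab in names(h$kinematics[[s]]$mounts)) {
      xf <- compose_transforms(xfs[[s]], h$kinematics[[s]]$mounts[[lab]])
      out[[lab]] <- transport_properties(h$local_props[[lab]], xf,
                                         frame = "global")
    }
  }
  out
}

#' Set joint angles
#'
#' Returns a model re-posed with the given configuration angles; other
#' angles keep their current values. Unknown names and out-of-bounds
#' values are errors.
#'
#' @param h A `"human"` model.
#' @param name Variable name (one of [configuration_names()]), or a named
#'   vector/list of several angles.
#' @param value Angle in radians (when `name` is a single name).
#' @param check_bounds Enforce [configuration_bounds()].
#' @return The updated `"human"`.
#' @examples \dontrun{
#' h <- set_configuration(h, "CA1adduction", -pi / 2)
#' h <- set_configuration(h, c(somersault = pi / 2, twist = 0.1))
#' }
#' @export
set_configuration <- function(h, name, value = NULL, check_bounds = TRUE) {
  stopifnot(inherits(h, "human"))
  upd <- if (is.character(name)) {
    if (is.null(value) || length(value) != length(name))
      stop("provide one value per configuration variable name", call. = FALSE)
    stats::setNames(as.numeric(value), name)
  } else name
  upd <- unlist(upd)
  if (is.null(names(upd))) stop("configuration angles must be named",
                                call. = FALSE)
  merged <- c(as.list(h$configuration)[setdiff(names(h$configuration),
                                               names(upd))],
              as.list(upd))
  h$configuration <- validate_configuration(merged,
                                            check_bounds = check_bounds)
  h
}

#' Whole-body inertial properties
#'
#' Mass, center of mass, and inertia tensor of the whole model in its
#' current configuration, expressed in the global frame, about either the
#' whole-body center of mass (default) or the global origin.
#'
#' @param h A `"human"` model.
#' @param about `"com"` or `"origin"`.
#' @return A [rigid_body()].
#' @export
whole_body_properties <- function(h, about = c("com", "origin")) {
  about <- match.arg(about)
  combine_rigid_bodies(solid_global_properties(h),
                       point = if (about == "com") "com" else c(0, 0, 0))
}

#' Combined inertial properties of solids and segments
#'
#' Aggregates any set of solid labels (`s0`-`s7`, `a0`-`a6`, `b0`-`b6`,
#' `j0`-`j8`, `k0`-`k8`) and/or segment labels (`P`, `T`, `C`, `A1`,
#' `A2`, `B1`, `B2`, `J1`, `J2`, `K1`, `K2`). Do not name a solid that is
#' part of a segment you have also named. The model is not modified.
#'
#' @param h A `"human"` model.
#' @param labels Character vector of solid and/or segment names.
#' @return A [rigid_body()]: summed mass, combined center of mass, and
#'   inertia tensor about the combined center of mass, in the global
#'   frame.
#' @export
combine_inertia <- function(h, labels) {
  stopifnot(inherits(h, "human"), is.character(labels), length(labels) > 0)
  segs <- segment_table()
  unknown <- setdiff(labels, c(names(segs), solid_names()))
  if (length(unknown) > 0)
    stop(sprintf("unknown solid/segment label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicated label(s) in combination", call. = FALSE)
  expanded <- lapply(labels, function(l)
    if (l %in% names(segs)) segs[[l]] else l)
  flat <- unlist(expanded)
  if (anyDuplicated(flat)) {
    dup <- unique(flat[duplicated(flat)])
    stop(sprintf(
      "overlapping specification: solid(s) %s named both directly and via a segment",
      paste(dup, collapse = ", ")), call. = FALSE)
  }
  combine_rigid_bodies(solid_global_properties(h)[flat], point = "com")
}

#' Whole-body inertia about an arbitrary point in an arbitrary frame
#'
#' Re-expresses the whole-body inertia tensor about `point` (global
#' coordinates) with axes given by `rotation`, whose columns are the
#' target frame's basis vectors expressed in the global frame (so
#' `I_new = R' I_global R`).
#'
#' @param h A `"human"` model.
#' @param point Reference point in global coordinates (m).
#' @param rotation 3x3 proper orthonormal matrix (target axes as columns).
#' @return 3x3 inertia tensor (kg m^2).
#' @export
inertia_transformed <- function(h, point = c(0, 0, 0), rotation = diag(3)) {
  xf <- frame_transform(rotation)  # validates orthonormality
  props <- shift_reference_point(whole_body_properties(h), point)
  t(xf$rotation) %*% props$inertia %*% xf$rotation
}

#' Scale the model to a measured total mass
#'
#' Multiplies every density — hence every solid mass and inertia entry —
#' by `target / mass(h)` so the model total mass equals `target`. Purely
#' geometric quantities (all positions, centers of mass) are unchanged.
#'
#' @param h A `"human"` model.
#' @param target Target total mass (kg, > 0).
#' @return The scaled `"human"`.
#' @export
scale_human_by_mass <- function(h, target) {
  stopifnot(inherits(h, "human"))
  if (!is.numeric(target) || length(target) != 1L || target <= 0)
    stop("target mass must be positive", call. = FALSE)
  current <- sum(vapply(h$local_props, function(p) p$mass, numeric(1)))
  f <- target / current
  h$densities <- scale_densities_to_mass(h$densities, current, target)
  h$local_props <- lapply(h$local_props, function(p)
    rigid_body(p$mass * f, p$com, p$inertia * f, p$frame, p$point))
  h
}

#' Per-segment masses
#'
#' @param h A `"human"` model.
#' @return Named numeric vector of the 11 segment masses (kg).
#' @export
segment_masses <- function(h) {
  stopifnot(inherits(h, "human"))
  masses <- vapply(h$local_props, function(p) p$mass, numeric(1))
  vapply(segment_table(), function(solids) sum(masses[solids]), numeric(1))
}

#' @export
print.human <- function(x, ...) {
  wb <- whole_body_properties(x)
  cat(sprintf("human model: 11 segments, 40 solids, mass %.4f kg\n", wb$mass))
  cat(sprintf("  com (global frame): (%.6g, %.6g, %.6g) m\n",
              wb$com[1], wb$com[2], wb$com[3]))
  nz <- x$configuration[x$configuration != 0]
  cat(if (length(nz) == 0) "  configuration: all 21 angles zero\n"
      else sprintf("  configuration: %s\n",
                   paste(sprintf("%s = %.3g", names(nz), nz),
                         collapse = ", ")))
  invisible(x)
}
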