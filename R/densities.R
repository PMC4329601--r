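#' Default solid densities
#'
#' Dempster's cadaver-derived segmental densities (Dempster 1955, as
#' tabulated for this geometric model by Yeadon 1990), assigned per solid:
#' head-neck 1110, shoulders 1040, thorax 920, abdomen-pelvis 1010, upper
#' arm 1070, forearm 1130, hand 1160, thigh 1050, lower leg 1090, foot
#' 1100 kg/m^3. Users may supply their own table anywhere a density table
#' is accepted.
#'
#' @param scale Multiplier applied to every density (used by mass-based
#'   scaling, see [scale_densities_to_mass()]).
#' @return Named numeric vector of length 40 (kg/m^3), one entry per
#'   solid, with attribute `scale_factor`.
#' @export
default_densities <- function(scale = 1) {
  group_density <- c(
    "abdomen-pelvis" = 1010, "thorax" = 920, "shoulders" = 1040,
    "head-neck" = 1110, "upper-arm" = 1070, "forearm" = 1130,
    "hand" = 1160, "thigh" = 1050, "lower-leg" = 1090, "foot" = 1100)
  tab <- solid_table()
  d <- scale * group_density[tab$group]
  names(d) <- tab$solid
  attr(d, "scale_factor") <- scale
  d
}

#' Uniform density table
#'
#' A density table assigning the same density to all 40 solids. Useful
#' for tests whose correctness must not depend on the Dempster constants.
#'
#' @param density Density in kg/m^3 (> 0).
#' @return Named numeric vector of length 40.
#' @export
uniform_densities <- function(density = 1000) {
  stopifnot(density > 0)
  d <- rep(density, length(solid_names()))
  names(d) <- solid_names()
  attr(d, "scale_factor") <- 1
  d
}

check_densities <- function(d) {
  nm <- solid_names()
  if (!is.numeric(d) || is.null(names(d)) || !setequal(names(d), nm))
    stop("density table must be a named numeric vector with one entry per solid",
         call. = FALSE)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("all densities must be positive", call. = FALSE)
  sf <- attr(d, "scale_factor")
  out <- d[nm]
  attr(out, "scale_factor") <- if (is.null(sf)) 1 else sf
  out
}

#' Scale densities to match a measured mass
#'
#' Multiplies every density by `target_mass / current_mass` so that a
#' model rebuilt with the returned table has total mass `target_mass`
#' (mass is linear in density). The cumulative factor is recorded in the
#' `scale_factor` attribute. Matching the measured total mass does not
#' guarantee that each segment's inertial estimate improves.
#'
#' @param d Density table (named numeric per solid).
#' @param current_mass Total mass of the model under `d` (kg, > 0).
#' @param target_mass Measured subject mass (kg, > 0).
#' @return Scaled density table.
#' @export
scale_densities_to_mass <- function(d, current_mass, target_mass) {
  d <- check_densities(d)
  if (!is.numeric(current_mass) || current_mass <= 0 ||
      !is.numeric(target_mass) || target_mass <= 0)
    stop("current and target masses must be positive", call. = FALSE)
  f <- target_mass / current_mass
  out <- d * f
  attr(out, "scale_factor") <- attr(d, "scale_factor") * f
  out
}
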