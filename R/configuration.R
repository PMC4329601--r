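# The 21 configuration variables. Each child segment is rotated relative
# to its parent by body-fixed X-Y-Z Euler angles; joints with fewer than
# three angles keep the same order. Names follow <parent><child><motion>;
# somersault/tilt/twist orient the pelvis P in the fixed frame. The signs
# follow the right-hand rule about the local axes: e.g. CA1adduction is
# positive for adduction of the left arm, so -pi/2 abducts it to
# horizontal, while CB1abduction is positive for abduction of the right
# arm.
configuration_table <- function() {
  tab <- rbind(
    data.frame(name = c("somersault", "tilt", "twist"),
               segment = "P", axis = c("x", "y", "z")),
    data.frame(name = c("PTsagittalFlexion", "PTbending"),
               segment = "T", axis = c("x", "y")),
    data.frame(name = c("TCsagittalSpinalFlexion", "TCspinalTorsion"),
               segment = "C", axis = c("x", "z")),
    data.frame(name = c("CA1extension", "CA1adduction", "CA1rotation"),
               segment = "A1", axis = c("x", "y", "z")),
    data.frame(name = "A1A2extension", segment = "A2", axis = "x"),
    data.frame(name = c("CB1extension", "CB1abduction", "CB1rotation"),
               segment = "B1", axis = c("x", "y", "z")),
    data.frame(name = "B1B2extension", segment = "B2", axis = "x"),
    data.frame(name = c("PJ1extension", "PJ1adduction"),
               segment = "J1", axis = c("x", "y")),
    data.frame(name = "J1J2flexion", segment = "J2", axis = "x"),
    data.frame(name = c("PK1extension", "PK1abduction"),
               segment = "K1", axis = c("x", "y")),
    data.frame(name = "K1K2flexion", segment = "K2", axis = "x"))
  tab$name <- as.character(tab$name)
  tab
}

#' Configuration variable names
#'
#' The 21 joint-angle names of the model, in canonical order.
#' @return Character vector of length 21.
#' @export
configuration_names <- function() configuration_table()$name

#' Configuration variable bounds
#'
#' Conservative physiological joint-angle limits (radians). These are
#' data, not anatomy: they keep the model away from grossly
#' unphysiological poses and can be overridden when setting angles with
#' `check_bounds = FALSE`.
#'
#' @return 2-column matrix (lower, upper) with one row per variable.
#' @export
configuration_bounds <- function() {
  b <- rbind(
    somersault = c(-pi, pi), tilt = c(-pi, pi), twist = c(-pi, pi),
    PTsagittalFlexion = c(-pi / 2, pi / 2), PTbending = c(-pi / 2, pi / 2),
    TCsagittalSpinalFlexion = c(-pi / 2, pi / 2),
    TCspinalTorsion = c(-pi / 2, pi / 2),
    CA1extension = c(-pi, pi / 2), CA1adduction = c(-pi, pi / 2),
    CA1rotation = c(-pi, pi),
    CB1extension = c(-pi, pi / 2), CB1abduction = c(-pi / 2, pi),
    CB1rotation = c(-pi, pi),
    A1A2extension = c(-pi, 0), B1B2extension = c(-pi, 0),
    PJ1extension = c(-pi, pi / 2), PJ1adduction = c(-pi / 2, pi / 2),
    PK1extension = c(-pi, pi / 2), PK1abduction = c(-pi / 2, pi / 2),
    J1J2flexion = c(0, pi), K1K2flexion = c(0, pi))
  colnames(b) <- c("lower", "upper")
  b[configuration_names(), , drop = FALSE]
}

zero_configuration <- function() {
  cfg <- rep(0, 21L)
  names(cfg) <- configuration_names()
  cfg
}

validate_configuration <- function(cfg, check_bounds = TRUE) {
  full <- zero_configuration()
  if (length(cfg) > 0) {
    if (is.null(names(cfg)))
      stop("configuration angles must be named", call. = FALSE)
    unknown <- setdiff(names(cfg), names(full))
    if (length(unknown) > 0)
      stop(sprintf("unknown configuration variable(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    v <- unlist(cfg)
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("configuration angles must be finite numbers", call. = FALSE)
    full[names(cfg)] <- v
  }
  if (check_bounds) {
    b <- configuration_bounds()
    bad <- which(full < b[, "lower"] - 1e-12 | full > b[, "upper"] + 1e-12)
    if (length(bad) > 0)
      stop(sprintf("configuration angle(s) out of bounds: %s",
                   paste(sprintf("%s = %.4g rad not in [%.4g, %.4g]",
                                 names(full)[bad], full[bad],
                                 b[bad, "lower"], b[bad, "upper"]),
                         collapse = "; ")), call. = FALSE)
  }
  full
}

#' Read a configuration file
#'
#' Reads joint angles (radians) from a YAML mapping of configuration
#' variable names to numbers. Omitted variables default to 0; unknown
#' names are rejected.
#'
#' @param path Path to a YAML configuration file.
#' @param check_bounds Enforce [configuration_bounds()].
#' @return Named numeric vector of length 21.
#' @export
read_configuration <- function(path, check_bounds = TRUE) {
  if (!file.exists(path))
    stop(sprintf("configuration file not found: '%s'", path), call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop(sprintf(
                    "malformed configuration file '%s': %s", path,
                    conditionMessage(e)), call. = FALSE))
  if (is.null(raw)) raw <- list()
  validate_configuration(raw, check_bounds = check_bounds)
}

# body-fixed X-Y-Z rotation for one segment from the full configuration
segment_rotation <- function(segment, cfg) {
  tab <- configuration_table()
  rows <- tab[tab$segment == segment, , drop = FALSE]
  r <- diag(3)
  for (ax in c("x", "y", "z")) {
    i <- which(rows$axis == ax)
    if (length(i) == 1L) {
      theta <- cfg[[rows$name[i]]]
      r <- r %*% switch(ax, x = rot_x(theta), y = rot_y(theta),
                        z = rot_z(theta))
    }
  }
  r
}
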