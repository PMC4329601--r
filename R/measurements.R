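#' Parse a measurement file
#'
#' Reads the 95 anthropometric measurements from YAML-formatted key/value
#' text. Keys are the measurement names (`Ls1L`, `La1p`, ...; see
#' [measurement_set()]); two optional extra keys are recognised:
#' `totalmass` (the subject's measured mass in kg, used by density
#' scaling) and `measurementconversionfactor` (a factor applied to every
#' measurement, e.g. `0.001` for data recorded in millimetres). All other
#' keys are rejected; missing measurements are reported by name.
#'
#' @param path Path to a YAML measurement file.
#' @param text YAML text given directly (overrides `path`).
#' @return A `"measurement_set"`: list with `values` (named numeric,
#'   length 95, meters), `total_mass` (kg or `NULL`), `conversion`.
#' @export
read_measurements <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path))
      stop(sprintf("measurement file not found: '%s'",
                   if (is.null(path)) "" else path), call. = FALSE)
    raw <- tryCatch(yaml::read_yaml(path),
                    error = function(e) stop(sprintf(
                      "malformed measurement file '%s': %s", path,
                      conditionMessage(e)), call. = FALSE))
  } else {
    raw <- tryCatch(yaml::yaml.load(text),
                    error = function(e) stop(sprintf(
                      "malformed measurement text: %s",
                      conditionMessage(e)), call. = FALSE))
  }
  if (!is.list(raw) || is.null(names(raw)))
    stop("measurement file must be a YAML mapping", call. = FALSE)

  conv <- raw[["measurementconversionfactor"]]
  if (is.null(conv)) conv <- 1
  total_mass <- raw[["totalmass"]]
  raw[["measurementconversionfactor"]] <- NULL
  raw[["totalmass"]] <- NULL

  wanted <- measurement_names()
  unknown <- setdiff(names(raw), wanted)
  if (length(unknown) > 0)
    stop(sprintf("unknown measurement key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  missing <- setdiff(wanted, names(raw))
  if (length(missing) > 0)
    stop(sprintf("missing measurement key(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)

  vals <- vapply(raw[wanted], function(v) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) NA_real_
    else as.numeric(v)
  }, numeric(1))
  bad <- wanted[is.na(vals) | vals <= 0]
  if (length(bad) > 0)
    stop(sprintf("non-numeric or non-positive measurement(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (!is.numeric(conv) || length(conv) != 1L || conv <= 0)
    stop("measurementconversionfactor must be a positive number",
         call. = FALSE)
  if (!is.null(total_mass) &&
      (!is.numeric(total_mass) || length(total_mass) != 1L || total_mass <= 0))
    stop("totalmass must be a positive number", call. = FALSE)

  measurement_set(vals * conv, total_mass = total_mass, conversion = conv)
}

#' Measurement set
#'
#' Constructs a validated set of the 95 anthropometric measurements (in
#' meters). Measurements follow the naming scheme `L<chain><level><type>`
#' with chain `s` (pelvis-torso-head), `a`/`b` (left/right arm), `j`/`k`
#' (left/right leg) and type `L` (cumulative length), `p` (perimeter),
#' `w` (mediolateral width), `d` (anteroposterior depth).
#'
#' @param values Named numeric vector holding exactly the 95 measurement
#'   names, all positive, in meters.
#' @param total_mass Optional measured subject mass (kg).
#' @param conversion Unit conversion factor already applied to `values`.
#' @return Object of class `"measurement_set"`.
#' @export
measurement_set <- function(values, total_mass = NULL, conversion = 1) {
  wanted <- measurement_names()
  stopifnot(is.numeric(values), !is.null(names(values)))
  missing <- setdiff(wanted, names(values))
  extra <- setdiff(names(values), wanted)
  if (length(missing) || length(extra))
    stop(sprintf("measurement_set: missing [%s], unknown [%s]",
                 paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")), call. = FALSE)
  values <- values[wanted]
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all measurements must be positive and finite", call. = FALSE)
  structure(list(values = values, total_mass = total_mass,
                 conversion = conversion),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("measurement set: %d measurements, stature-chain height %.3f m%s\n",
              length(x$values),
              x$values[["Ls5L"]] + x$values[["Ls8L"]] +
                x$values[["Lj5L"]] + x$values[["Lj9L"]],
              if (is.null(x$total_mass)) ""
              else sprintf(", measured mass %.1f kg", x$total_mass)))
  invisible(x)
}

#' Write a measurement file
#'
#' Emits the YAML dialect read by [read_measurements()], in canonical key
#' order and at full precision, so that `read_measurements()` of the
#' output reproduces the input exactly.
#'
#' @param m A `"measurement_set"`.
#' @param path Output path; if `NULL`, the YAML text is returned.
#' @return The YAML text, invisibly when written to a file.
#' @export
write_measurements <- function(m, path = NULL) {
  stopifnot(inherits(m, "measurement_set"))
  lines <- c("# anthropometric measurements (meters)",
             "measurementconversionfactor: 1",
             if (!is.null(m$total_mass))
               sprintf("totalmass: %.17g", m$total_mass),
             sprintf("%s: %.17g", names(m$values), m$values))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(text)
}

#' Average left and right limb measurements
#'
#' Replaces every left/right measurement pair (arm chains `a`/`b`, leg
#' chains `j`/`k`) with its arithmetic mean, producing a bilaterally
#' symmetric subject. Torso measurements are untouched. Applying the
#' operation twice equals applying it once.
#'
#' @param m A `"measurement_set"`.
#' @return A symmetric `"measurement_set"`.
#' @export
average_limbs <- function(m) {
  stopifnot(inherits(m, "measurement_set"))
  v <- m$values
  avg <- (v + v[mirror_measurement(names(v))]) / 2
  names(avg) <- names(v)
  measurement_set(avg, total_mass = m$total_mass, conversion = m$conversion)
}

# Build the stadium (or semiellipsoid placeholder) for one level.
build_level_stadium <- function(level, recipe, vals, ls0 = NULL, ls4 = NULL) {
  g <- function(ty) vals[[paste0(level, ty)]]
  switch(recipe,
    pw   = stadium(p = g("p"), w = g("w"), label = level),
    wd   = stadium(w = g("w"), d = g("d"), label = level),
    circ = stadium(p = g("p"), label = level),
    heel = stadium(p = g("p"), w = g("d"), orientation = "AP",
                   label = level),
    hip  = stadium(r = sqrt(ls0$r * 2 * (ls0$t + ls0$r)) / 2, t = 0,
                   label = level),
    acromion = {
      r <- 0.57 * ls4$r
      stadium(r = r, t = (ls4$t + ls4$r) - r, label = level)
    },
    apex = NULL,
    stop("unknown level recipe ", recipe))
}

#' Resolve levels and solids from measurements
#'
#' Converts a measurement set into the full geometric inventory of the
#' model: the 45 level cross-sections (stadia), their longitudinal
#' positions along each chain, and the 40 solids grouped into 11
#' segments. Cumulative length measurements are differenced into per-solid
#' heights; implicit levels (mid upper arm, mid-thigh, foot arch) are
#' placed midway between their measured neighbours; the internal acromion
#' stadium atop the shoulder solid is derived from the `Ls4` stadium
#' (`r = 0.57 r_Ls4`, `t = w_Ls4/2 - r`); and the unmeasured hip stadia
#' `Lj0`/`Lk0` are circles of radius `sqrt(r_Ls0 w_Ls0)/2`. Heel stadia
#' are anteroposterior. Measured perimeter/width pairs whose ratio falls
#' outside `(2, pi)` are downgraded to circles with a warning.
#'
#' @param m A `"measurement_set"`.
#' @param densities Named numeric density per solid (kg/m^3); see
#'   [default_densities()].
#' @return A `"solid_stack"`: list with `levels` (named list of stadia),
#'   `positions` (named numeric), `solids` (named list of
#'   `stadium_solid`/`semiellipsoid`), and `segments` (solid labels per
#'   segment).
#' @export
resolve_levels <- function(m, densities = default_densities()) {
  stopifnot(inherits(m, "measurement_set"))
  vals <- as.list(m$values)
  densities <- check_densities(densities)

  levels <- list(); positions <- numeric(0)
  ls0 <- NULL; ls4 <- NULL
  for (chain in c("s", "a", "b", "j", "k")) {
    pos <- level_positions(vals, chain)
    recipes <- level_recipes(chain)
    for (lev in names(recipes)) {
      levels[[lev]] <- build_level_stadium(lev, recipes[[lev]], vals,
                                           ls0 = ls0, ls4 = ls4)
      if (lev == "Ls0") ls0 <- levels[[lev]]
      if (lev == "Ls4") ls4 <- levels[[lev]]
    }
    positions <- c(positions, pos)
  }
  levels[["Ls5acromion"]] <- build_level_stadium("Ls5acromion", "acromion",
                                                 vals, ls4 = ls4)

  tab <- solid_table()
  solids <- vector("list", nrow(tab))
  names(solids) <- tab$solid
  for (i in seq_len(nrow(tab))) {
    lab <- tab$solid[i]
    bot <- tab$bottom[i]; top <- tab$top[i]
    h <- positions[[top]] - positions[[bot]]
    if (!is.finite(h) || h <= 0)
      stop(sprintf(
        "measurement ordering violated: level %s (%.4g m) not above %s (%.4g m)",
        top, positions[[top]], bot, positions[[bot]]), call. = FALSE)
    rho <- densities[[lab]]
    if (lab == "s7") {
      base <- levels[["Ls7"]]
      solids[[lab]] <- semiellipsoid(a = base$t + base$r, b = base$r,
                                     c = h, density = rho, label = lab)
    } else {
      top_st <- if (lab == "s4") levels[["Ls5acromion"]] else levels[[top]]
      solids[[lab]] <- stadium_solid(levels[[bot]], top_st, h, rho,
                                     label = lab)
    }
  }

  structure(list(levels = levels, positions = positions, solids = solids,
                 segments = segment_table()),
            class = "solid_stack")
}
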