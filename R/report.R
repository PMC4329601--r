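#' Format an inertial-properties report
#'
#' Serialises a [rigid_body()] as fixed-width text or as JSON. The JSON
#' form stores the six unique entries of the symmetric tensor at full
#' precision, so parsing the output reproduces the numbers exactly; the
#' text form is fixed-width for reading. Properties containing
#' non-finite numbers are refused.
#'
#' @param props A [rigid_body()].
#' @param format `"text"` or `"json"`.
#' @param title Optional heading (text format).
#' @return A character string.
#' @export
write_report <- function(props, format = c("text", "json"), title = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(props, "rigid_body"))
  nums <- c(props$mass, props$com, props$inertia, props$point)
  if (any(!is.finite(nums)))
    stop("refusing to report non-finite inertial properties", call. = FALSE)
  i <- props$inertia
  if (format == "json") {
    obj <- list(
      mass_kg = props$mass,
      com_m = props$com,
      inertia_kgm2 = list(ixx = i[1, 1], iyy = i[2, 2], izz = i[3, 3],
                          ixy = i[1, 2], ixz = i[1, 3], iyz = i[2, 3]),
      frame = props$frame,
      about_point_m = props$point)
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                         digits = NA, pretty = TRUE)))
  }
  fmt3 <- function(v) sprintf("% .10e % .10e % .10e", v[1], v[2], v[3])
  paste(c(
    if (!is.null(title)) title,
    sprintf("frame: %s, inertia about point (%g, %g, %g) m",
            props$frame, props$point[1], props$point[2], props$point[3]),
    sprintf("mass (kg):      % .10e", props$mass),
    sprintf("com (m):       %s", fmt3(props$com)),
    "inertia (kg m^2):",
    sprintf("               %s", fmt3(i[1, ])),
    sprintf("               %s", fmt3(i[2, ])),
    sprintf("               %s", fmt3(i[3, ]))),
    collapse = "\n")
}

#' Parse a JSON report
#'
#' Inverse of [write_report()]'s JSON format.
#'
#' @param text JSON text produced by `write_report(..., format = "json")`.
#' @return A [rigid_body()].
#' @export
read_report <- function(text) {
  obj <- jsonlite::fromJSON(text)
  it <- obj$inertia_kgm2
  inertia <- matrix(c(it$ixx, it$ixy, it$ixz,
                      it$ixy, it$iyy, it$iyz,
                      it$ixz, it$iyz, it$izz), 3, 3)
  rigid_body(obj$mass_kg, obj$com_m, inertia, obj$frame, obj$about_point_m)
}

cli_usage <- function() {
  paste(
    "usage: anthroinertia --meas FILE [options]",
    "       anthroinertia --seed-fixture N",
    "",
    "Body segment inertial parameters from anthropometric measurements.",
    "",
    "options:",
    "  --meas FILE        YAML measurement file (95 measurements)",
    "  --config FILE      YAML joint-angle file (radians, omitted = 0)",
    "  --symmetric        average left and right limb measurements",
    "  --scale-mass KG    scale densities to this total mass",
    "  --combine LABELS   comma-separated solid/segment labels; report",
    "                     their combined properties about the combined com",
    "  --about POINT      origin|com (whole-body report; default com)",
    "  --format FMT       text|json (default text)",
    "  --seed-fixture N   print a synthetic measurement file for seed N",
    "  --help             show this message",
    sep = "\n")
}

cli_parse_args <- function(args) {
  opts <- list(meas = NULL, config = NULL, symmetric = FALSE,
               scale_mass = NULL, combine = NULL, about = "com",
               format = "text", seed_fixture = NULL, help = FALSE)
  i <- 1L
  need <- function(flag) {
    if (i + 1L > length(args)) stop(sprintf("%s requires a value", flag),
                                    call. = FALSE)
    args[[i + 1L]]
  }
  while (i <= length(args)) {
    a <- args[[i]]
    if (a == "--help") { opts$help <- TRUE }
    else if (a == "--symmetric") { opts$symmetric <- TRUE }
    else if (a == "--meas") { opts$meas <- need(a); i <- i + 1L }
    else if (a == "--config") { opts$config <- need(a); i <- i + 1L }
    else if (a == "--scale-mass") {
      opts$scale_mass <- as.numeric(need(a)); i <- i + 1L }
    else if (a == "--combine") { opts$combine <- need(a); i <- i + 1L }
    else if (a == "--about") { opts$about <- need(a); i <- i + 1L }
    else if (a == "--format") { opts$format <- need(a); i <- i + 1L }
    else if (a == "--seed-fixture") {
      opts$seed_fixture <- as.integer(need(a)); i <- i + 1L }
    else stop(sprintf("unknown argument '%s'", a), call. = FALSE)
    i <- i + 1L
  }
  opts
}

#' Command-line interface
#'
#' Drives the full pipeline from shell-style arguments: read a
#' measurement file (and optional configuration file), build the model,
#' and print mass, center of mass, and inertia tensor — whole-body or for
#' a combination of solids/segments — as text or JSON on standard
#' output. Warnings (e.g. circle downgrades) go to standard error. With
#' `--seed-fixture N` a synthetic measurement file is printed instead.
#'
#' @param args Character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit code, invisibly: 0 on success, 1 on error.
#' @examples
#' run_cli(c("--seed-fixture", "7"))
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    opts <- cli_parse_args(args)
    if (opts$help || (is.null(opts$meas) && is.null(opts$seed_fixture))) {
      cat(cli_usage(), "\n")
      return(invisible(if (opts$help) 0L else 1L))
    }
    if (!is.null(opts$seed_fixture)) {
      m <- generate_synthetic_measurements(seed = opts$seed_fixture)
      cat(write_measurements(m))
      return(invisible(0L))
    }
    if (!opts$format %in% c("text", "json"))
      stop("--format must be 'text' or 'json'", call. = FALSE)
    if (!opts$about %in% c("origin", "com"))
      stop("--about must be 'origin' or 'com'", call. = FALSE)

    m <- read_measurements(opts$meas)
    cfg <- if (!is.null(opts$config)) read_configuration(opts$config)
    h <- human_model(m, symmetric = opts$symmetric, configuration = cfg)
    if (!is.null(opts$scale_mass)) {
      if (!is.finite(opts$scale_mass) || opts$scale_mass <= 0)
        stop("--scale-mass must be a positive number", call. = FALSE)
      h <- scale_human_by_mass(h, opts$scale_mass)
    }
    if (!is.null(opts$combine)) {
      labels <- trimws(strsplit(opts$combine, ",")[[1]])
      props <- combine_inertia(h, labels)
      title <- sprintf("combined properties of [%s]",
                       paste(labels, collapse = ", "))
    } else {
      props <- whole_body_properties(h, about = opts$about)
      title <- "whole-body properties"
    }
    cat(write_report(props, format = opts$format, title = title), "\n")
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
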