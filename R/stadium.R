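#' Stadium cross-section
#'
#' A stadium is the 2D shape formed by a rectangle of half-width (thickness)
#' `t` and half-height `r`, capped on both sides by semicircles of radius
#' `r`. It is the cross-sectional shape of almost every level of the body
#' model; with `t = 0` it degenerates to a circle. A stadium is determined
#' by any two of its five attributes: perimeter `p`, radius `r`, thickness
#' `t`, total width `w = 2(t + r)` and depth `d = 2r`.
#'
#' Supported attribute pairs are `r`+`t` (direct), `p`+`w`, `p`+`d`,
#' `w`+`d`, and `p` alone (a circle). Measured perimeter/width pairs must
#' satisfy `2 < p/w < pi`; pairs violating this cannot describe a stadium
#' and are downgraded to a circle (recovered from the perimeter when a
#' perimeter was supplied, else from the width) with a warning. The
#' boundary ratios are degenerate but valid: `p/w = pi` is a circle
#' (`t = 0`), `p/w = 2` a flat rectangle (`r = 0`).
#'
#' @param r,t,p,w,d Numeric scalars; supply exactly one supported pair (or
#'   `p` alone). All lengths in meters.
#' @param orientation `"ML"` (mediolateral, wide axis along x) or `"AP"`
#'   (anteroposterior, wide axis along y; used only for the heel levels).
#' @param label Optional name carried along for error messages.
#' @return An object of class `"stadium"` with fields `r`, `t`,
#'   `orientation`, `label`.
#' @examples
#' stadium(p = 10, w = 4)          # general stadium
#' stadium(w = 4, d = 2)           # r = 1, t = 1
#' stadium(p = 2 * pi)             # circle of radius 1
#' @export
stadium <- function(r = NULL, t = NULL, p = NULL, w = NULL, d = NULL,
                    orientation = c("ML", "AP"), label = "") {
  orientation <- match.arg(orientation)
  got <- c(r = !is.null(r), t = !is.null(t), p = !is.null(p),
           w = !is.null(w), d = !is.null(d))
  for (nm in names(got)[got]) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("stadium %s: attribute '%s' must be a nonnegative finite number",
                   label, nm), call. = FALSE)
  }
  pair <- paste(sort(names(got)[got]), collapse = "+")

  if (pair == "r+t") {
    # direct; allow r = 0 (flat) and t = 0 (circle)
  } else if (pair == "p+w") {
    if (p <= 0 || w <= 0)
      stop(sprintf("stadium %s: p and w must be positive", label), call. = FALSE)
    ratio <- p / w
    if (ratio >= 2 && ratio <= pi) {
      r <- (p - 2 * w) / (2 * pi - 4)
      t <- w / 2 - r
    } else {
      warning(sprintf(
        "stadium %s: perimeter/width ratio %.4f outside (2, pi); assuming a circle (r = p/(2*pi))",
        label, ratio), call. = FALSE)
      r <- p / (2 * pi)
      t <- 0
    }
  } else if (pair == "d+p") {
    if (p <= 0 || d <= 0)
      stop(sprintf("stadium %s: p and d must be positive", label), call. = FALSE)
    r <- d / 2
    t <- (p - pi * d) / 4
    if (t < 0) {
      warning(sprintf(
        "stadium %s: perimeter %.4f smaller than pi*depth; assuming a circle (r = p/(2*pi))",
        label, p), call. = FALSE)
      r <- p / (2 * pi)
      t <- 0
    }
  } else if (pair == "d+w") {
    if (w <= 0 || d <= 0)
      stop(sprintf("stadium %s: w and d must be positive", label), call. = FALSE)
    if (d > w)
      stop(sprintf("stadium %s: depth %.4f exceeds width %.4f (impossible geometry)",
                   label, d, w), call. = FALSE)
    r <- d / 2
    t <- (w - d) / 2
  } else if (pair == "p") {
    if (p <= 0)
      stop(sprintf("stadium %s: p must be positive", label), call. = FALSE)
    r <- p / (2 * pi)
    t <- 0
  } else {
    stop(sprintf("stadium %s: unsupported attribute combination '%s'",
                 label, pair), call. = FALSE)
  }

  structure(list(r = r, t = t, orientation = orientation, label = label),
            class = "stadium")
}

#' Stadium attributes
#'
#' Derived attributes of a [stadium()]: perimeter `p = 4t + 2*pi*r`, width
#' `w = 2(t + r)`, depth `d = 2r`, and area `A = 4rt + pi*r^2`.
#'
#' @param s A `"stadium"` object.
#' @return Named numeric vector with elements `r`, `t`, `p`, `w`, `d`, `area`.
#' @export
stadium_attributes <- function(s) {
  stopifnot(inherits(s, "stadium"))
  c(r = s$r, t = s$t,
    p = 4 * s$t + 2 * pi * s$r,
    w = 2 * (s$t + s$r),
    d = 2 * s$r,
    area = 4 * s$r * s$t + pi * s$r^2)
}

#' @export
print.stadium <- function(x, ...) {
  a <- stadium_attributes(x)
  kind <- if (x$t == 0) "circle" else "stadium"
  cat(sprintf("%s%s: r = %.4g m, t = %.4g m (p = %.4g, w = %.4g), %s\n",
              kind, if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              a["r"], a["t"], a["p"], a["w"], x$orientation))
  invisible(x)
}

is_circle <- function(s) s$t == 0
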