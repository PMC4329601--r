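# Template measurement values (meters) for a plausible adult of roughly
# 1.7 m stature and 65-70 kg build. Chosen so that every measured
# perimeter/width pair satisfies 2 < p/w < pi with margin, cumulative
# lengths increase within every measurement block, and the default
# densities yield a total mass well inside the human range. Limb values
# are bilaterally symmetric; the generator applies asymmetry jitter.
measurement_template <- function() {
  torso <- c(
    Ls1L = 0.15, Ls2L = 0.25, Ls3L = 0.40, Ls4L = 0.52, Ls5L = 0.60,
    Ls6L = 0.10, Ls7L = 0.14, Ls8L = 0.26,
    Ls0p = 0.94, Ls1p = 0.85, Ls2p = 0.85, Ls3p = 0.92, Ls5p = 0.38,
    Ls6p = 0.55, Ls7p = 0.57,
    Ls0w = 0.36, Ls1w = 0.32, Ls2w = 0.31, Ls3w = 0.33, Ls4w = 0.42,
    Ls4d = 0.24)
  arm <- c("2L" = 0.30, "3L" = 0.33, "4L" = 0.55, "5L" = 0.04,
           "6L" = 0.095, "7L" = 0.185,
           "0p" = 0.30, "1p" = 0.28, "2p" = 0.26, "3p" = 0.25,
           "4p" = 0.16, "5p" = 0.205, "6p" = 0.20, "7p" = 0.12,
           "4w" = 0.055, "5w" = 0.075, "6w" = 0.085, "7w" = 0.05)
  leg <- c("1L" = 0.08, "3L" = 0.42, "4L" = 0.54, "5L" = 0.82,
           "6L" = 0.065, "8L" = 0.16, "9L" = 0.23,
           "1p" = 0.58, "2p" = 0.52, "3p" = 0.38, "4p" = 0.37,
           "5p" = 0.225, "6p" = 0.32, "7p" = 0.24, "8p" = 0.245,
           "9p" = 0.155,
           "8w" = 0.095, "9w" = 0.06, "6d" = 0.11)
  limb <- function(v, chain) stats::setNames(v, paste0("L", chain, names(v)))
  c(torso, limb(arm, "a"), limb(arm, "b"), limb(leg, "j"), limb(leg, "k"))
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic measurement set
#'
#' Produces a complete, valid 95-measurement set from an internal adult
#' template. Lengths scale with `stature_scale` and girths (perimeters,
#' widths, depths) with `girth_scale`; left/right asymmetry is introduced
#' by jittering each limb's lengths and each limb level's girths by
#' uniform factors in `1 +/- asymmetry`. Girth jitter is applied jointly
#' to a level's perimeter and width so every perimeter/width ratio stays
#' strictly inside `(2, pi)` by construction, and length jitter is a
#' common per-limb factor so cumulative lengths stay strictly increasing
#' within every measurement block. Deterministic for a given `seed`.
#'
#' @param stature_scale,girth_scale Positive scale factors (default 1).
#' @param asymmetry Left/right jitter fraction in `[0, 0.2]` (default
#'   0.05; 0 gives exactly equal limbs).
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   state.
#' @param total_mass Optional measured mass (kg) to store with the set.
#' @return A `"measurement_set"`.
#' @examples
#' m <- generate_synthetic_measurements(seed = 42)
#' @export
generate_synthetic_measurements <- function(stature_scale = 1,
                                            girth_scale = 1,
                                            asymmetry = 0.05,
                                            seed = NULL,
                                            total_mass = NULL) {
  stopifnot(stature_scale > 0, girth_scale > 0,
            asymmetry >= 0, asymmetry <= 0.2)
  v <- measurement_template()
  type <- substr(names(v), nchar(names(v)), nchar(names(v)))
  v[type == "L"] <- v[type == "L"] * stature_scale
  v[type != "L"] <- v[type != "L"] * girth_scale

  v <- with_local_seed(seed, {
    for (chain in c("a", "b", "j", "k")) {
      in_chain <- substr(names(v), 2, 2) == chain
      len <- in_chain & type == "L"
      v[len] <- v[len] * stats::runif(1, 1 - asymmetry, 1 + asymmetry)
      # joint girth factor per level keeps p/w ratios intact
      levels <- unique(substr(names(v)[in_chain & type != "L"], 1, 3))
      for (lev in levels) {
        girth <- in_chain & type != "L" & substr(names(v), 1, 3) == lev
        v[girth] <- v[girth] * stats::runif(1, 1 - asymmetry, 1 + asymmetry)
      }
    }
    v
  })
  measurement_set(v, total_mass = total_mass)
}
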