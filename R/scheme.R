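# Declarative description of the measurement scheme: which measurements
# exist, how each level's stadium is built from them, where each level sits
# along its segment chain, and how solids and segments are assembled from
# the levels. Everything downstream (parsing, model assembly, fixtures)
# reads these tables; none of it is hard-coded elsewhere.

#' Measurement name inventory
#'
#' The 95 measurement names in canonical order. Naming:
#' `L<chain><level><type>` with type `L` = cumulative length, `p` =
#' perimeter, `w` = mediolateral width, `d` = anteroposterior depth;
#' chains `s` = pelvis/torso/head, `a`/`b` = left/right arm, `j`/`k` =
#' left/right leg.
#'
#' @return Character vector of length 95.
#' @export
measurement_names <- function() {
  torso <- c(paste0("Ls", 1:8, "L"),
             paste0("Ls", c(0:3, 5:7), "p"),
             paste0("Ls", 0:4, "w"),
             "Ls4d")
  arm <- function(x) c(paste0("L", x, 2:7, "L"),
                       paste0("L", x, 0:7, "p"),
                       paste0("L", x, 4:7, "w"))
  leg <- function(x) c(paste0("L", x, c(1, 3:6, 8, 9), "L"),
                       paste0("L", x, 1:9, "p"),
                       paste0("L", x, 8:9, "w"),
                       paste0("L", x, 6, "d"))
  c(torso, arm("a"), arm("b"), leg("j"), leg("k"))
}

# Longitudinal positions of every level along its chain, from the chain
# origin (Ls0, La0/Lb0 shoulder, Lj0/Lk0 hip). Length measurements are
# cumulative within blocks: torso levels 1-5 are measured from level 0 and
# levels 6-8 restart from level 5; arm levels 2-4 from level 0 and 5-7
# from level 4; leg levels 1, 3-6 from level 0/level 5 and 8-9 from level
# 5. Implicit levels: La1 (mid upper arm) at La2L/2, and the analogous
# mid-limb levels Lj2 (mid-thigh, midway between crotch and knee) and Lj7
# (foot arch, midway between heel and ball).
level_positions <- function(vals, chain) {
  g <- function(nm) vals[[nm]]
  if (chain == "s") {
    z <- c(0, g("Ls1L"), g("Ls2L"), g("Ls3L"), g("Ls4L"), g("Ls5L"),
           g("Ls5L") + g("Ls6L"), g("Ls5L") + g("Ls7L"),
           g("Ls5L") + g("Ls8L"))
    names(z) <- paste0("Ls", 0:8)
  } else if (chain %in% c("a", "b")) {
    p <- function(i, ty = "L") g(paste0("L", chain, i, ty))
    z <- c(0, p(2) / 2, p(2), p(3), p(4),
           p(4) + p(5), p(4) + p(6), p(4) + p(7))
    names(z) <- paste0("L", chain, 0:7)
  } else {
    p <- function(i, ty = "L") g(paste0("L", chain, i, ty))
    z <- c(0, p(1), (p(1) + p(3)) / 2, p(3), p(4), p(5),
           p(5) + p(6), p(5) + (p(6) + p(8)) / 2,
           p(5) + p(8), p(5) + p(9))
    names(z) <- paste0("L", chain, 0:9)
  }
  z
}

# Stadium construction recipe per level: how = pw (perimeter+width),
# wd (width+depth), circ (perimeter alone), acromion (internal, from the
# Ls4 stadium: r = 0.57 r_Ls4, t = w_Ls4/2 - r), hip (internal circle,
# r = sqrt(r_Ls0 * w_Ls0) / 2), apex (top of the head, no stadium). The
# heel levels Lj6/Lk6 are the only anteroposterior stadia; their measured
# depth is the width of a stadium rotated through 90 degrees.
level_recipes <- function(chain) {
  if (chain == "s") {
    list(Ls0 = "pw", Ls1 = "pw", Ls2 = "pw", Ls3 = "pw", Ls4 = "wd",
         Ls5 = "circ", Ls6 = "circ", Ls7 = "circ", Ls8 = "apex")
  } else if (chain %in% c("a", "b")) {
    r <- c("circ", "circ", "circ", "circ", "pw", "pw", "pw", "pw")
    names(r) <- paste0("L", chain, 0:7)
    as.list(r)
  } else {
    r <- c("hip", rep("circ", 5), "heel", "circ", "pw", "pw")
    names(r) <- paste0("L", chain, 0:9)
    as.list(r)
  }
}

# Solid inventory: 40 solids, their bounding levels and density group.
# Solid <x>N is bounded below (proximally) by level L<x>N and above by
# L<x>(N+1); s4's top is the internal acromion stadium and s7 is the
# cranial semi-ellipsoid based at Ls7 reaching the apex Ls8.
solid_table <- function() {
  seg <- function(chain, idx, group)
    data.frame(solid = paste0(chain, idx),
               chain = chain,
               bottom = paste0("L", chain, idx),
               top = paste0("L", chain, idx + 1),
               group = group,
               stringsAsFactors = FALSE)
  rbind(
    seg("s", 0:1, "abdomen-pelvis"),
    seg("s", 2:3, "thorax"),
    seg("s", 4, "shoulders"),
    seg("s", 5:7, "head-neck"),
    seg("a", 0:1, "upper-arm"), seg("a", 2:3, "forearm"),
    seg("a", 4:6, "hand"),
    seg("b", 0:1, "upper-arm"), seg("b", 2:3, "forearm"),
    seg("b", 4:6, "hand"),
    seg("j", 0:2, "thigh"), seg("j", 3:4, "lower-leg"),
    seg("j", 5:8, "foot"),
    seg("k", 0:2, "thigh"), seg("k", 3:4, "lower-leg"),
    seg("k", 5:8, "foot"))
}

#' Segment partition
#'
#' The 11 rigid segments and the solids composing each: `P` pelvis
#' (s0-s1), `T` thorax (s2), `C` chest-head (s3-s7), `A1`/`B1` left/right
#' upper arm, `A2`/`B2` forearm-hand, `J1`/`K1` left/right thigh,
#' `J2`/`K2` shank-foot.
#'
#' @return Named list: solid labels per segment.
#' @export
segment_table <- function() {
  list(P  = paste0("s", 0:1),
       T  = "s2",
       C  = paste0("s", 3:7),
       A1 = paste0("a", 0:1),
       A2 = paste0("a", 2:6),
       B1 = paste0("b", 0:1),
       B2 = paste0("b", 2:6),
       J1 = paste0("j", 0:2),
       J2 = paste0("j", 3:8),
       K1 = paste0("k", 0:2),
       K2 = paste0("k", 3:8))
}

segment_names <- function() names(segment_table())

#' Solid labels
#'
#' The 40 solid labels (`s0`-`s7`, `a0`-`a6`, `b0`-`b6`, `j0`-`j8`,
#' `k0`-`k8`) in canonical order.
#' @return Character vector of length 40.
#' @export
solid_names <- function() solid_table()$solid

# left/right measurement pairing used by limb averaging
mirror_measurement <- function(nm) {
  chartr("abjk", "bakj", nm)
}
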