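# shared helpers: relative errors, random valid solids, tensor checks

rel_err <- function(got, want) {
  scale <- max(abs(want))
  if (scale == 0) return(max(abs(got)))
  max(abs(got - want)) / scale
}

random_stadium_solid <- function(allow_circles = TRUE) {
  t_lo <- if (allow_circles && stats::runif(1) < 0.3) 0 else 0.005
  stadium_solid(
    stadium(r = stats::runif(1, 0.02, 0.15),
            t = if (t_lo == 0) 0 else stats::runif(1, t_lo, 0.1)),
    stadium(r = stats::runif(1, 0.02, 0.15),
            t = if (allow_circles && stats::runif(1) < 0.3) 0
                else stats::runif(1, 0.005, 0.1)),
    height = stats::runif(1, 0.05, 0.5),
    density = stats::runif(1, 500, 2000))
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

expect_valid_tensor <- function(props, tol = 1e-10) {
  i <- props$inertia
  expect_lt(max(abs(i - t(i))), tol * max(1, max(abs(i))))
  ev <- sort(eigen((i + t(i)) / 2, symmetric = TRUE)$values)
  scale <- max(abs(ev))
  expect_gte(ev[1], -tol * scale)
  # principal moments of a physical body satisfy triangle inequalities
  expect_gte(ev[1] + ev[2] - ev[3], -tol * scale)
}
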