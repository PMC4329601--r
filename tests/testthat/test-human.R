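sym_meas <- generate_synthetic_measurements(asymmetry = 0)
sym_h <- human_model(sym_meas, uniform_densities())

test_that("the assembled model has the canonical structure", {
  expect_length(sym_h$stack$segments, 11)
  expect_length(sym_h$stack$solids, 40)
  expect_length(sym_h$stack$positions, 45)
  expect_length(sym_h$configuration, 21)
  expect_true(all(sym_h$configuration == 0))
  # zero configuration: every solid's global rotation is the identity,
  # apart from the 90-degree in-plane turn of the anteroposterior heels
  xfs <- anthroinertia:::segment_transforms(sym_h)
  for (s in names(xfs)) expect_equal(xfs[[s]]$rotation, diag(3))
  # total mass is conserved across solids and segments
  wb <- whole_body_properties(sym_h)
  masses <- vapply(sym_h$local_props, function(p) p$mass, numeric(1))
  expect_equal(wb$mass, sum(masses), tolerance = 1e-12)
  expect_equal(sum(segment_masses(sym_h)), sum(masses), tolerance = 1e-12)
})

test_that("zero-configuration geometry is anatomically placed", {
  props <- anthroinertia:::solid_global_properties(sym_h)
  v <- sym_meas$values
  # pelvis origin at the bottom center of s0; head apex at Ls5L + Ls8L
  expect_equal(props$s0$point, c(0, 0, 0))
  expect_equal(props$s7$com[3],
               unname(v["Ls5L"] + v["Ls7L"]) +
                 solid_properties(sym_h$stack$solids$s7)$com[3])
  # arms hang from the shoulders, building downward from level Ls4
  expect_equal(props$a0$point[3], unname(v["Ls4L"]))
  expect_lt(props$a6$com[3], props$a0$com[3])
  # left/right placement: left limbs at +x, right at -x
  expect_gt(props$a0$com[1], 0); expect_lt(props$b0$com[1], 0)
  expect_gt(props$j0$com[1], 0); expect_lt(props$k0$com[1], 0)
  # hip joint centers at +/- (t_Ls0 + r_Ls0)/2
  ls0 <- sym_h$stack$levels$Ls0
  expect_equal(props$j0$point, c((ls0$t + ls0$r) / 2, 0, 0))
  expect_equal(props$k0$point, c(-(ls0$t + ls0$r) / 2, 0, 0))
  # legs extend below the origin
  expect_lt(props$j8$com[3], props$j0$com[3])
})

test_that("a symmetric model at zero configuration is sagittally balanced", {
  wb <- whole_body_properties(sym_h)
  expect_lt(abs(wb$com[1]), 1e-14)
  expect_lt(abs(wb$inertia[1, 2]), 1e-12)
  expect_lt(abs(wb$inertia[1, 3]), 1e-12)
  # left and right limb segment masses match exactly after averaging
  sm <- segment_masses(human_model(
    generate_synthetic_measurements(asymmetry = 0.1, seed = 3),
    uniform_densities(), symmetric = TRUE))
  expect_equal(sm[["A1"]], sm[["B1"]], tolerance = 1e-12)
  expect_equal(sm[["J2"]], sm[["K2"]], tolerance = 1e-12)
})

test_that("setting configuration angles validates names and bounds", {
  expect_error(set_configuration(sym_h, "elbowTwist", 0.1), "elbowTwist")
  expect_error(set_configuration(sym_h, "K1K2flexion", -2), "bounds")
  expect_silent(h2 <- set_configuration(sym_h, "K1K2flexion", 2))
  expect_equal(h2$configuration[["K1K2flexion"]], 2)
  # unchecked setting permits exotic poses
  h3 <- set_configuration(sym_h, "K1K2flexion", -2, check_bounds = FALSE)
  expect_equal(h3$configuration[["K1K2flexion"]], -2)
})

test_that("whole-model rotations act as rigid rotations of the inertia tensor", {
  w0 <- whole_body_properties(sym_h, about = "origin")
  for (cfg in list(c(somersault = pi / 2),
                   c(tilt = 0.4),
                   c(somersault = 0.3, tilt = -0.2, twist = 1.1))) {
    hr <- set_configuration(sym_h, cfg)
    wr <- whole_body_properties(hr, about = "origin")
    ang <- function(nm) if (nm %in% names(cfg)) cfg[[nm]] else 0
    r <- rot_x(ang("somersault")) %*% rot_y(ang("tilt")) %*%
      rot_z(ang("twist"))
    expect_equal(wr$mass, w0$mass)
    expect_lt(rel_err(wr$inertia, r %*% w0$inertia %*% t(r)), 1e-12)
    expect_equal(wr$com, as.numeric(r %*% w0$com), tolerance = 1e-12)
  }
})

test_that("configuration round-trips and changes only the distal subtree", {
  posed <- set_configuration(sym_h, c(PTsagittalFlexion = 0.3,
                                      CA1adduction = -1.0,
                                      J1J2flexion = 0.8))
  back <- set_configuration(posed, c(PTsagittalFlexion = 0,
                                     CA1adduction = 0, J1J2flexion = 0))
  w0 <- whole_body_properties(sym_h, about = "origin")
  wb <- whole_body_properties(back, about = "origin")
  expect_lt(rel_err(wb$inertia, w0$inertia), 1e-12)
  expect_equal(wb$com, w0$com, tolerance = 1e-14)

  # a knee rotation must leave every solid outside the shank-foot intact
  bent <- set_configuration(sym_h, "K1K2flexion", 1.2)
  p0 <- anthroinertia:::solid_global_properties(sym_h)
  p1 <- anthroinertia:::solid_global_properties(bent)
  moved <- segment_table()$K2
  for (lab in names(p0)) {
    if (lab %in% moved) {
      expect_false(isTRUE(all.equal(p0[[lab]]$com, p1[[lab]]$com)))
    } else {
      expect_identical(p0[[lab]]$com, p1[[lab]]$com)
      expect_identical(p0[[lab]]$inertia, p1[[lab]]$inertia)
    }
  }
})

test_that("combine_inertia aggregates exactly and rejects overlaps", {
  wb <- whole_body_properties(sym_h)  # about com
  all_segs <- names(segment_table())
  cb <- combine_inertia(sym_h, all_segs)
  expect_equal(cb$mass, wb$mass, tolerance = 1e-12)
  expect_equal(cb$com, wb$com, tolerance = 1e-12)
  expect_lt(rel_err(cb$inertia, wb$inertia), 1e-12)

  # singleton: one solid equals its transported properties
  s0 <- combine_inertia(sym_h, "s0")
  direct <- anthroinertia:::solid_global_properties(sym_h)$s0
  expect_equal(s0$mass, direct$mass)
  expect_lt(rel_err(s0$inertia, shift_reference_point(direct, direct$com)$inertia),
            1e-12)

  expect_error(combine_inertia(sym_h, c("B1", "b0")), "overlap")
  expect_error(combine_inertia(sym_h, c("P", "P")), "duplicated")
  expect_error(combine_inertia(sym_h, "Q3"), "Q3")
})

test_that("inertia_transformed honors point and rotation arguments", {
  wb <- whole_body_properties(sym_h)
  # identity at the origin equals the whole-body tensor about the origin
  expect_lt(rel_err(inertia_transformed(sym_h),
                    whole_body_properties(sym_h, about = "origin")$inertia),
            1e-12)
  # the tensor about the com is minimal in the positive-semidefinite order
  set.seed(31)
  for (i in 1:5) {
    p <- stats::rnorm(3, sd = 0.5)
    diffm <- inertia_transformed(sym_h, point = p) -
      inertia_transformed(sym_h, point = wb$com)
    ev <- eigen((diffm + t(diffm)) / 2, symmetric = TRUE)$values
    expect_gte(min(ev), -1e-10)
    # any rotation preserves the spectrum
    r <- random_rotation()
    expect_equal(sort(eigen(inertia_transformed(sym_h, p, r))$values),
                 sort(eigen(inertia_transformed(sym_h, p))$values),
                 tolerance = 1e-10)
  }
  expect_error(inertia_transformed(sym_h, rotation = matrix(1, 3, 3)),
               "orthonormal")
})

test_that("mass scaling is exact, linear in inertia, and com-invariant", {
  wb <- whole_body_properties(sym_h)
  h60 <- scale_human_by_mass(sym_h, 60)
  wb60 <- whole_body_properties(h60)
  expect_equal(wb60$mass, 60, tolerance = 1e-13)
  f <- 60 / wb$mass
  expect_lt(rel_err(wb60$inertia, f * wb$inertia), 1e-12)
  expect_equal(wb60$com, wb$com, tolerance = 1e-14)
  expect_equal(segment_masses(h60), f * segment_masses(sym_h),
               tolerance = 1e-12)
  # no-op and error cases
  expect_equal(whole_body_properties(
    scale_human_by_mass(sym_h, wb$mass))$mass, wb$mass, tolerance = 1e-14)
  expect_error(scale_human_by_mass(sym_h, -3), "positive")
  # a measured total mass in the measurement set triggers the scaling
  m2 <- sym_meas; m2$total_mass <- 58.2
  expect_equal(whole_body_properties(human_model(m2))$mass, 58.2,
               tolerance = 1e-12)
})

test_that("an ice skater spins up by pulling the arms in", {
  for (seed in c(1, 2, 3)) {
    h <- human_model(generate_synthetic_measurements(seed = seed))
    down <- whole_body_properties(h)$inertia[3, 3]
    out <- whole_body_properties(set_configuration(
      h, c(CA1adduction = -pi / 2, CB1abduction = pi / 2)))$inertia[3, 3]
    expect_gt(out / down, 1)
  }
})

test_that("all tensors produced across an assembled model are physical", {
  h <- human_model(generate_synthetic_measurements(seed = 8),
                   configuration = c(somersault = 0.5, K1K2flexion = 1.0,
                                     CA1adduction = -0.7,
                                     TCspinalTorsion = 0.3))
  for (p in anthroinertia:::solid_global_properties(h)) expect_valid_tensor(p)
  expect_valid_tensor(whole_body_properties(h))
  expect_valid_tensor(whole_body_properties(h, about = "origin"))
})
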