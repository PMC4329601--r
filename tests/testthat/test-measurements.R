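base_meas <- generate_synthetic_measurements(asymmetry = 0)

test_that("the measurement inventory has the canonical counts", {
  nm <- measurement_names()
  expect_length(nm, 95)
  expect_false(anyDuplicated(nm) > 0)
  # 4 types, tied to levels of the five chains
  expect_true(all(grepl("^L[sabjk][0-9][Lpwd]$", nm)))
})

test_that("measurement files parse, validate and round-trip", {
  text <- write_measurements(base_meas)
  m <- read_measurements(text = text)
  expect_identical(m$values, base_meas$values)

  path <- withr::local_tempfile(fileext = ".yml")
  write_measurements(base_meas, path)
  expect_identical(read_measurements(path)$values, base_meas$values)

  # missing key reported by name
  broken <- sub("Ls2L: [0-9.e+-]+\n", "", text)
  expect_error(read_measurements(text = broken), "Ls2L")
  # unknown key rejected
  expect_error(read_measurements(text = paste0(text, "Lx9q: 1\n")), "Lx9q")
  # non-positive value rejected by name
  bad <- sub("Lj5p: [0-9.e+-]+", "Lj5p: -0.2", text)
  expect_error(read_measurements(text = bad), "Lj5p")
  # missing file reported with its path
  expect_error(read_measurements("/no/such/file.yml"), "/no/such/file.yml")
})

test_that("unit conversion factors rescale measurements on input", {
  v <- base_meas$values * 1000  # millimetres
  lines <- c("measurementconversionfactor: 0.001",
             sprintf("%s: %.17g", names(v), v))
  m <- read_measurements(text = paste(lines, collapse = "\n"))
  expect_equal(m$values, base_meas$values, tolerance = 1e-12)
  expect_equal(m$conversion, 0.001)
})

test_that("limb averaging symmetrises and is idempotent", {
  m <- generate_synthetic_measurements(asymmetry = 0.15, seed = 21)
  expect_false(isTRUE(all.equal(m$values[["La2p"]], m$values[["Lb2p"]])))
  avg <- average_limbs(m)
  expect_equal(unname(avg$values["La2p"]),
               unname((m$values["La2p"] + m$values["Lb2p"]) / 2))
  # left/right equal after averaging; torso untouched
  a_keys <- grep("^La", names(avg$values), value = TRUE)
  expect_equal(unname(avg$values[a_keys]),
               unname(avg$values[chartr("a", "b", a_keys)]))
  expect_identical(avg$values[grep("^Ls", names(avg$values))],
                   m$values[grep("^Ls", names(m$values))])
  expect_identical(average_limbs(avg)$values, avg$values)
  # an already symmetric set is a fixed point
  expect_identical(average_limbs(base_meas)$values, base_meas$values)
})

test_that("levels difference into per-solid heights per the length blocks", {
  stack <- resolve_levels(base_meas, uniform_densities())
  v <- base_meas$values
  # torso block: s-chain lengths cumulative from Ls0, restarting at Ls5
  expect_equal(stack$solids$s0$height, unname(v["Ls1L"]))
  expect_equal(stack$solids$s1$height, unname(v["Ls2L"] - v["Ls1L"]))
  expect_equal(stack$solids$s5$height, unname(v["Ls6L"]))
  expect_equal(stack$solids$s7$c, unname(v["Ls8L"] - v["Ls7L"]))
  # implicit mid upper arm level at half the shoulder-elbow length
  expect_equal(stack$solids$a0$height, unname(v["La2L"]) / 2)
  expect_equal(stack$solids$a1$height, unname(v["La2L"]) / 2)
  # foot block restarts at the ankle
  expect_equal(stack$solids$j5$height, unname(v["Lj6L"]))
  # arch midway between heel and ball
  expect_equal(stack$solids$j6$height, unname((v["Lj8L"] - v["Lj6L"]) / 2))
  # 45 levels, 40 solids, 11 segments
  expect_length(stack$positions, 45)
  expect_length(stack$solids, 40)
  expect_length(stack$segments, 11)
})

test_that("internal stadia follow the acromion and hip-circle relations", {
  stack <- resolve_levels(base_meas, uniform_densities())
  ls4 <- stack$levels$Ls4
  acr <- stack$levels$Ls5acromion
  w4 <- 2 * (ls4$t + ls4$r)
  expect_equal(acr$r, 0.57 * ls4$r, tolerance = 1e-14)
  expect_equal(acr$t, w4 / 2 - 0.57 * ls4$r, tolerance = 1e-14)

  ls0 <- stack$levels$Ls0
  w0 <- 2 * (ls0$t + ls0$r)
  expect_equal(stack$levels$Lj0$r, sqrt(ls0$r * w0) / 2, tolerance = 1e-14)
  expect_identical(stack$levels$Lj0$t, 0)
  expect_identical(stack$levels$Lk0$r, stack$levels$Lj0$r)

  # substitution check on the acromion relations
  m2 <- base_meas
  m2$values["Ls4w"] <- 0.20; m2$values["Ls4d"] <- 0.10  # r = 0.05
  acr2 <- resolve_levels(m2, uniform_densities())$levels$Ls5acromion
  expect_equal(acr2$r, 0.0285, tolerance = 1e-14)
  expect_equal(acr2$t, 0.0715, tolerance = 1e-14)

  # only the heel stadia are anteroposterior
  ap <- names(Filter(function(s) !is.null(s) && s$orientation == "AP",
                     stack$levels))
  expect_setequal(ap, c("Lj6", "Lk6"))
})

test_that("violated measurement ordering is reported with the level pair", {
  m2 <- base_meas
  m2$values["Ls1L"] <- m2$values[["Ls2L"]] + 0.05
  expect_error(resolve_levels(m2, uniform_densities()), "Ls2.*Ls1")
})

test_that("an out-of-range measured perimeter/width is downgraded with a warning", {
  m2 <- base_meas
  m2$values["Ls1w"] <- m2$values[["Ls1p"]]  # ratio 1 < 2
  expect_warning(stack <- resolve_levels(m2, uniform_densities()), "circle")
  expect_identical(stack$levels$Ls1$t, 0)
  expect_equal(stack$levels$Ls1$r, base_meas$values[["Ls1p"]] / (2 * pi),
               tolerance = 1e-14)
})

test_that("density tables validate and scale linearly with target mass", {
  d <- default_densities()
  expect_length(d, 40)
  expect_true(all(d > 0))
  expect_identical(scale_densities_to_mass(d, 58.2, 58.2), d)
  d2 <- scale_densities_to_mass(d, 50, 100)
  expect_equal(as.numeric(d2), as.numeric(2 * d))
  expect_equal(attr(d2, "scale_factor"), 2)
  expect_error(scale_densities_to_mass(d, -1, 2), "positive")

  # model mass is linear in a common density factor
  m0 <- whole_body_properties(human_model(base_meas, d))$mass
  m1 <- whole_body_properties(human_model(base_meas, d2))$mass
  expect_equal(m1, 2 * m0, tolerance = 1e-12)
})
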