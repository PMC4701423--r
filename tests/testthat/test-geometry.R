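test_that("center spacing reproduces the reference dextran500 table", {
  L <- center_spacing(dextran500, ref_spacing$c)
  # the reference table carries a small (~0.04%) rounding drift in its
  # fuller-precision rows; the formula matches within 0.05% everywhere and
  # digit-for-digit at the 1-decimal rows
  expect_equal(L, ref_spacing$L, tolerance = 5e-4)
  expect_equal(round(L[1], 1), 160.7)
  expect_equal(round(L[12], 1), 25.5)
  # cube-root scaling: an 8-fold concentration increase halves the spacing
  expect_equal(center_spacing(dextran500, 8), center_spacing(dextran500, 1) / 2)
})

test_that("center spacing scales as c^(-1/3) and rejects bad input", {
  cs <- 10^seq(-1, 2, length.out = 7)
  L <- center_spacing(5e5, cs)
  expect_true(all(diff(L) < 0))
  expect_equal(L * cs^(1 / 3), rep(L[1] * cs[1]^(1 / 3), 7))
  expect_error(center_spacing(5e5, -1), "positive")
  expect_error(center_spacing(-5, 1), "positive")
  # unit conversions: 1 % w/v = 10 mg/ml
  expect_equal(center_spacing(5e5, 1, unit = "percent"),
               center_spacing(5e5, 10, unit = "mg/ml"))
})

test_that("rho is 2(R+a)/L with its limiting cases", {
  expect_equal(rho_parameter(2, 0.5, 5), 1)       # touching spheres
  expect_equal(rho_parameter(0, 0, 123), 0)
  expect_equal(rho_parameter(15.9, 1.8, 160.7), 0.2203, tolerance = 1e-4)
  expect_error(rho_parameter(1, 1, 0), "positive")
  expect_error(rho_parameter(-1, 1, 5), ">= 0")
  # rho increases with concentration for fixed radii
  rho <- rho_parameter(15.9, 1.8, center_spacing(dextran500, c(1, 5, 25)))
  expect_true(all(diff(rho) > 0))
})

test_that("obstructed fraction covers both regimes and matches a sampling oracle", {
  expect_equal(obstructed_fraction(0), 0)
  expect_equal(obstructed_fraction(1), pi / 6)
  # overlapping regime: frozen inclusion-exclusion value, cross-checked
  # against the point-sampling oracle
  expect_equal(obstructed_fraction(1.2), 0.7979645, tolerance = 1e-6)
  est <- phi_oracle(1.2, 3e5, seed = 42)
  se <- sqrt(est * (1 - est) / 3e5)
  expect_lt(abs(est - obstructed_fraction(1.2)), 4 * se)
  # continuity at rho = 1 and monotonicity up to sqrt(2)
  expect_equal(obstructed_fraction(1 - 1e-9), obstructed_fraction(1 + 1e-9),
               tolerance = 1e-7)
  grid <- seq(0, 1.41, by = 0.01)
  expect_true(all(diff(obstructed_fraction(grid)) > 0))
  expect_error(obstructed_fraction(sqrt(2)), "disconnected")
})

test_that("overlap concentrations follow the two defining formulas", {
  # coil overlap: Rg = 19.95 nm reproduces the 2.5 % w/v reference value
  p <- polymer_spec("d500", 500, 15.9, rg = 19.95, mw_unit = "kDa")
  expect_equal(round(overlap_concentration(p), 1), 2.5)
  # cubic scaling and the identity case
  p2 <- polymer_spec("d500", 500, 15.9, rg = 2 * 19.95, mw_unit = "kDa")
  expect_equal(overlap_concentration(p2), overlap_concentration(p) / 8)
  rg_id <- (3 / (4 * pi * 6.022e23) * 1e21 * 500e3 / 0.01)^(1 / 3)
  pid <- polymer_spec("id", 500, 10, rg = rg_id, mw_unit = "kDa")
  expect_equal(overlap_concentration(pid), 1, tolerance = 1e-12)
  expect_error(overlap_concentration(dextran500), "R_g")

  # geometric overlap: dextran70 prints as 7.4 % w/v at one decimal
  expect_equal(round(geometric_overlap_concentration(dextran70), 1), 7.4)
  expect_equal(geometric_overlap_concentration(dextran500), 2.58,
               tolerance = 2e-3)
  # ratio of the two definitions
  expect_equal(geometric_overlap_concentration(p) / overlap_concentration(p),
               (4 / 3) * pi * 19.95^3 / (8 * 15.9^3))
})

test_that("spheres touch exactly at the geometric overlap concentration", {
  for (p in list(dextran500, dextran70)) {
    ctheta <- geometric_overlap_concentration(p)
    L <- center_spacing(p, ctheta, unit = "percent")
    expect_equal(rho_parameter(p$hydrodynamic_radius, 0, L), 1,
                 tolerance = 1e-12)
  }
})

test_that("system geometry assembles the pieces and guards the void", {
  geo <- system_geometry(dextran500, rnase, 5)
  expect_s3_class(geo, "system_geometry")
  expect_equal(geo$L, center_spacing(dextran500, 5))
  expect_equal(geo$rho, rho_parameter(15.9, 1.8, geo$L))
  expect_equal(geo$phi, obstructed_fraction(geo$rho))
  # far above the geometric overlap the void disconnects
  expect_error(system_geometry(dextran500, rnase, 60), "sqrt\\(2\\)")
})

test_that("the shipped library matches the constructors", {
  lib <- polymer_library()
  expect_named(lib, c("polymers", "solutes"))
  d500 <- lib$polymers$dextran500
  expect_equal(d500$molecular_weight, 5e5)
  expect_equal(d500$hydrodynamic_radius, 15.9)
  expect_equal(attr(d500, "cstar_percent"), 2.5)
  expect_equal(lib$solutes$rnase$hydrodynamic_radius, 1.8)
})
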