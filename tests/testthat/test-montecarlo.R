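test_that("reflect_segment handles free, head-on and grazing segments", {
  # no obstruction in the way: straight translation
  end <- reflect_segment(c(2.5, 2.5, 2.5), c(0.3, -0.2, 0.1), rho = 0.6, L = 5)
  expect_equal(end, c(2.8, 2.3, 2.6))
  # head-on radial approach to the sphere at the origin reflects straight
  # back with distances preserved: start at x = 2, surface at 1.5, step -1
  # travels 0.5 in, 0.5 back out
  end <- reflect_segment(c(2, 0, 0), c(-1, 0, 0), rho = 0.6, L = 5)
  expect_equal(end, c(2, 0, 0), tolerance = 1e-9)
  # exactly tangent contact counts as no collision
  r <- 0.6 * 5 / 2
  end <- reflect_segment(c(-2, r, 0), c(4, 0, 0), rho = 0.6, L = 5)
  expect_equal(end, c(2, r, 0))
  # starting inside an obstruction violates the invariant
  expect_error(reflect_segment(c(0.1, 0, 0), c(1, 0, 0), rho = 0.6, L = 5),
               "inside")
})

test_that("oblique reflection preserves path length and stays outside", {
  r <- 0.6 * 5 / 2
  start <- c(2.0, 0.4, -0.3)
  disp <- c(-1.4, -0.1, 0.2)
  end <- reflect_segment(start, disp, rho = 0.6, L = 5)
  # endpoint outside every obstruction
  d <- end - 5 * round(end / 5)
  expect_gte(sqrt(sum(d^2)), r * (1 - 1e-9))
  # total path length preserved: |start -> hit| + |hit -> end| = |disp|
  # (recover the hit point from the ray-sphere intersection)
  u <- disp / sqrt(sum(disp^2))
  b <- 2 * sum(u * start)
  cc <- sum(start^2) - r^2
  s <- (-b - sqrt(b^2 - 4 * cc)) / 2
  hit <- start + s * u
  len <- s + sqrt(sum((end - hit)^2))
  expect_equal(len, sqrt(sum(disp^2)), tolerance = 1e-9)
})

test_that("initial positions respect the chosen mode", {
  cfg <- walk_config("wiener", rho = 0.9, L = 5, n_walks = 10, seed = 1)
  expect_equal(initial_position(cfg), c(2.5, 2.5, 2.5))
  cfgu <- walk_config("wiener", rho = 0.9, L = 5, n_walks = 10,
                      init = "uniform", seed = 1)
  set.seed(99)
  pts <- t(replicate(500, initial_position(cfgu)))
  r <- 0.9 * 5 / 2
  d <- pts - 5 * round(pts / 5)
  expect_true(all(rowSums(d^2) >= r^2))
  expect_true(all(pts >= 0 & pts < 5))
})

test_that("ensembles are reproducible from the seed and start at MSD = 0", {
  cfg <- walk_config("wiener", rho = 0.6, n_walks = 50, n_record = 20,
                     t_max = 5, seed = 31)
  e1 <- simulate_wiener(cfg)
  e2 <- simulate_wiener(cfg)
  expect_identical(e1$sq_disp, e2$sq_disp)
  e3 <- simulate_wiener(walk_config("wiener", rho = 0.6, n_walks = 50,
                                    n_record = 20, t_max = 5, seed = 32))
  expect_false(identical(e1$sq_disp, e3$sq_disp))
  expect_equal(e1$times[1], 0)
  expect_true(all(e1$sq_disp[, 1] == 0))
  expect_true(all(e1$sq_disp >= 0))

  ck <- walk_config("kinetic", rho = 0.6, n_walks = 50, n_record = 20,
                    t_max = 5, seed = 31)
  k1 <- simulate_kinetic(ck)
  k2 <- simulate_kinetic(ck)
  expect_identical(k1$sq_disp, k2$sq_disp)
  expect_true(all(k1$sq_disp[, 1] == 0))
})

test_that("no recorded position lies inside an obstruction", {
  for (model in c("wiener", "kinetic")) {
    cfg <- walk_config(model, rho = 1.0, n_walks = 150, n_record = 50,
                       t_max = 20, init = "uniform", seed = 7)
    ens <- simulate_ensemble(cfg, record_positions = TRUE)
    expect_true(crowddiff:::.positions_clear(ens))
  }
})

test_that("both models reproduce free diffusion when unobstructed", {
  cfg <- walk_config("wiener", rho = 0, n_walks = 3000, t_max = 20,
                     dt = 0.02, seed = 41)
  fw <- fit_de(simulate_wiener(cfg))
  expect_gt(1, fw$ci95[1]); expect_lt(1, fw$ci95[2])

  ck <- walk_config("kinetic", rho = 0, n_walks = 3000, t_max = 20, seed = 42)
  ensk <- simulate_kinetic(ck)
  fk <- fit_de(ensk)
  # large-t asymptote: MSD/t -> 2 lambda^2 / tau = 6 D0
  expect_equal(2 * ck$lambda^2 / ck$tau, 6)
  expect_gt(1, fk$ci95[1]); expect_lt(1, fk$ci95[2])
  # MSD curve itself approaches slope 6 at late times
  msd <- estimate_msd(ensk)
  late <- msd$time >= 10
  expect_equal(mean(msd$msd[late] / msd$time[late]), 6, tolerance = 0.1)
})

test_that("obstruction lowers the fitted diffusivity below D0", {
  cfg <- walk_config("wiener", rho = 0.8, n_walks = 2000, seed = 51)
  f <- fit_de(simulate_wiener(cfg))
  expect_lt(f$ci95[2], 1)
})

test_that("default kinetic step duration follows tau = lambda^2 / (3 D0)", {
  cfg <- walk_config("kinetic", rho = 0.5)
  expect_equal(cfg$tau, 0.04 / 3)
  cfg2 <- walk_config("kinetic", rho = 0.5, D0 = 2, lambda = 0.1)
  expect_equal(cfg2$tau, 0.01 / 6)
})

test_that("configuration guards reject unusable parameters", {
  expect_error(walk_config("wiener", rho = 2.5), "\\[0, 2\\)")
  expect_error(walk_config("wiener", rho = 0.6, dt = 1), "too large")
  expect_warning(walk_config("wiener", rho = 1.99, dt = 1e-4, n_walks = 10),
                 "disconnected")
  expect_error(walk_config("wiener", rho = 0.6, t_max = -1), "positive")
})
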