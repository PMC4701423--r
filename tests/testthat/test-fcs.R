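delays_default <- 10^seq(-6.5, -1, length.out = 80)

test_that("autocorrelation model has the right limits", {
  n <- 4; tau_d <- 5e-5; p <- 0.04
  expect_equal(fcs_model(1e3, n, tau_d, p), 1, tolerance = 1e-4)
  expect_equal(fcs_model(1e-12, n, tau_d, p), 1 + 1 / n, tolerance = 1e-6)
  # at tau = tau_d with a vanishing structure constant: 1 + 1/(2N)
  expect_equal(fcs_model(tau_d, n, tau_d, 1e-12), 1 + 1 / (2 * n),
               tolerance = 1e-6)
  g <- fcs_model(delays_default, n, tau_d, p)
  expect_true(all(diff(g) < 0))
})

test_that("fitting a noiseless synthetic curve recovers the parameters", {
  curve <- synthesize_fcs(n = 5, tau_d = 5e-5, p = 0.04,
                          delays = delays_default)
  fit <- fit_fcs(curve, p = 0.04)
  expect_equal(fit$n_particles, 5, tolerance = 1e-6)
  expect_equal(fit$tau_d, 5e-5, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
  expect_error(fit_fcs(curve[1:5, ], p = 0.04), "at least 10")
})

test_that("fitted tau_d is nearly unbiased under 1% amplitude noise", {
  # noise_sd = 0.002 on an amplitude swing of 1/N = 0.2 is a 1% noise level
  reps <- vapply(1:100, function(i) {
    curve <- synthesize_fcs(n = 5, tau_d = 5e-5, p = 0.04,
                            delays = delays_default, noise_sd = 0.002,
                            seed = 1000 + i)
    fit_fcs(curve, p = 0.04)$tau_d
  }, 0)
  expect_lt(abs(mean(reps) / 5e-5 - 1), 0.02)
})

test_that("diffusion-time conversions invert each other", {
  # calibration-dye reference: D = 2.8e-10 m^2/s at r0 = 208 nm
  expect_equal(diffusivity_to_diffusion_time(2.8e-10, r0 = 208), 3.863e-5,
               tolerance = 1e-4)
  expect_equal(diffusion_time_to_diffusivity(3.863e-5, r0 = 208), 2.8e-10,
               tolerance = 1e-4)
  # doubling r0 quadruples tau_d at fixed D
  expect_equal(diffusivity_to_diffusion_time(1e-10, r0 = 416),
               4 * diffusivity_to_diffusion_time(1e-10, r0 = 208))
  d <- 1.7e-10
  expect_equal(diffusion_time_to_diffusivity(diffusivity_to_diffusion_time(d)), d)
})

test_that("normalized diffusivity is the ratio of diffusion times", {
  expect_equal(normalized_diffusivity(4e-5, 4e-5), 1)
  expect_equal(normalized_diffusivity(4e-5, 8e-5), 0.5)
  expect_warning(normalized_diffusivity(8e-5, 4e-5), "faster than free")
})

test_that("coefficient of determination behaves per definition", {
  obs <- c(1, 2, 3, 5, 8)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 5)), 0)
  expect_lt(r_squared(obs, rev(obs)), 0)     # worse than the mean
  expect_error(r_squared(rep(2, 4), rep(2, 4)), "undefined")
  expect_error(r_squared(1:3, 1:4), "equal-length")
})

test_that("synthetic curves are reproducible and carry the requested noise", {
  c1 <- synthesize_fcs(3, 4e-5, 0.04, delays_default, noise_sd = 0.01, seed = 5)
  c2 <- synthesize_fcs(3, 4e-5, 0.04, delays_default, noise_sd = 0.01, seed = 5)
  expect_identical(c1, c2)
  c3 <- synthesize_fcs(3, 4e-5, 0.04, delays_default, noise_sd = 0.01, seed = 6)
  expect_false(identical(c1, c3))
  # noiseless curve equals the model exactly
  c0 <- synthesize_fcs(3, 4e-5, 0.04, delays_default)
  expect_equal(c0$G, fcs_model(delays_default, 3, 4e-5, 0.04))
  # empirical noise SD matches over many points
  big <- seq(1e-6, 1e-1, length.out = 4000)
  cn <- synthesize_fcs(3, 4e-5, 0.04, big, noise_sd = 0.01, seed = 7)
  expect_equal(sd(cn$G - fcs_model(big, 3, 4e-5, 0.04)), 0.01,
               tolerance = 0.05)
})

test_that("curves round-trip through CSV files", {
  curve <- synthesize_fcs(5, 5e-5, 0.04, delays_default)
  path <- tempfile(fileext = ".csv")
  write_fcs(curve, path)
  back <- read_fcs(path)
  expect_equal(back$delay_s, curve$delay_s)
  expect_equal(back$G, curve$G)
  unlink(path)
  expect_error(fcs_curve(c(2e-5, 1e-5), c(1.1, 1.2)), "increasing")
})

test_that("an emulated concentration series round-trips through the FCS model", {
  # geometry -> homogenization -> synthetic curves -> refit -> De/D0:
  # the recovered normalized diffusivities must match the model curve
  lib <- polymer_library()
  sw <- homogenization_sweep(seq(0, 1.2, by = 0.1), n = 32)
  pred <- predict_diffusivity(lib$polymers$dextran500, lib$solutes$rnase,
                              c(0.5, 3, 10), sweep = sw)
  tau_0 <- 1e-4
  recovered <- vapply(pred$De_over_D0, function(de) {
    curve <- synthesize_fcs(n = 5, tau_d = tau_0 / de, p = 0.04,
                            delays = 10^seq(-6, 0, length.out = 90),
                            noise_sd = 0.001, seed = round(1e4 * de))
    normalized_diffusivity(tau_0, fit_fcs(curve, p = 0.04)$tau_d)
  }, 0)
  expect_equal(recovered, pred$De_over_D0, tolerance = 0.02)
})
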