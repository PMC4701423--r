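test_that("MSD estimator averages per-walk squared displacements", {
  times <- seq(0, 4, by = 1)
  # all walkers stationary
  ens0 <- fake_ensemble(times, matrix(0, nrow = 4, ncol = 5))
  m0 <- estimate_msd(ens0)
  expect_true(all(m0$msd == 0) && all(m0$stderr == 0))
  # two walkers at fixed displacements d and -d: msd = d^2, stderr from the
  # two-point sample
  d <- 1.5
  sq <- rbind(rep(d^2, 5), rep((-d)^2, 5))
  sq[, 1] <- 0
  m2 <- estimate_msd(fake_ensemble(times, sq))
  expect_equal(m2$msd[-1], rep(d^2, 4))
  expect_equal(m2$stderr[-1], rep(0, 4))   # both walks give the same square
  expect_error(estimate_msd(fake_ensemble(times, sq[1, , drop = FALSE])),
               "at least 2")
})

test_that("free-diffusion MSD over the recorded window is 6 D0 t", {
  cfg <- walk_config("wiener", rho = 0, n_walks = 10000, t_max = 10,
                     dt = 0.04, n_record = 50, seed = 61)
  msd <- estimate_msd(simulate_wiener(cfg))
  ratio <- msd$msd[-1] / msd$time[-1]
  expect_equal(mean(ratio), 6, tolerance = 0.2)
})

test_that("through-origin slope fitting is exact on exact lines", {
  times <- seq(0, 10, length.out = 20)
  for (s in c(6, 3)) {
    sq <- matrix(rep(s * times, each = 40), nrow = 40)
    est <- fit_de(fake_ensemble(times, sq))
    expect_equal(est$slope, s)
    expect_equal(est$De, s / 6)
    # identical deterministic walks: zero-width interval
    expect_equal(est$ci95[1], est$ci95[2])
    expect_warning(fit_de(fake_ensemble(times, sq[1:3, ])), "fewer than 30")
  }
  expect_error(fit_de(fake_ensemble(times, matrix(0, 40, 20))), "all-zero")
})

test_that("per-walk CI half-width scales as 1/sqrt(N)", {
  times <- seq(0, 10, length.out = 20)
  set.seed(71)
  mk <- function(n) {
    slopes <- 6 + rnorm(n, sd = 1.5)
    fake_ensemble(times, outer(slopes, times))
  }
  w1 <- diff(fit_de(mk(1000))$ci95)
  w2 <- diff(fit_de(mk(16000))$ci95)
  expect_equal(w1 / w2, 4, tolerance = 0.3)
})

test_that("bootstrap and per-walk intervals broadly agree", {
  times <- seq(0, 10, length.out = 20)
  set.seed(72)
  ens <- fake_ensemble(times, outer(6 + rnorm(500, sd = 1), times))
  a <- fit_de(ens, ci = "perwalk")
  b <- fit_de(ens, ci = "bootstrap")
  expect_equal(a$De, b$De)
  expect_equal(diff(a$ci95), diff(b$ci95), tolerance = 0.25)
})

test_that("msd-curve fitting falls back to a t-based interval", {
  curve <- structure(data.frame(time = seq(0, 5, 0.5),
                                msd = 6 * seq(0, 5, 0.5)),
                     class = c("msd_curve", "data.frame"))
  expect_warning(est <- fit_de(curve), "t-based")
  expect_equal(est$De, 1)
})

test_that("log-log diagnostic recovers power laws", {
  t <- 10^seq(-2, 2, length.out = 60)
  # pure normal diffusion, D0 = 1: alpha = 1, C = 6
  curve <- structure(data.frame(time = c(0, t), msd = c(0, 6 * t)),
                     class = c("msd_curve", "data.frame"))
  fit <- loglog_diagnostic(curve, n_segments = 1)
  expect_equal(fit$exponents, 1, tolerance = 1e-10)
  expect_equal(fit$intercepts, 6, tolerance = 1e-10)
  # subdiffusive synthetic input: alpha recovered within 0.02
  curve2 <- structure(data.frame(time = t, msd = 2.5 * t^0.8),
                      class = c("msd_curve", "data.frame"))
  fit2 <- loglog_diagnostic(curve2, n_segments = 1)
  expect_equal(fit2$exponents, 0.8, tolerance = 0.02)
  expect_equal(fit2$intercepts, 2.5, tolerance = 0.02)
  expect_error(loglog_diagnostic(curve2, n_segments = 40), "fewer points")
})

test_that("piecewise fit finds a two-regime transition and stays continuous", {
  t <- 10^seq(-2, 2, length.out = 80)
  msd <- ifelse(t < 1, 6 * t, 6 * t^0.6)   # kink at t = 1
  curve <- structure(data.frame(time = t, msd = msd),
                     class = c("msd_curve", "data.frame"))
  fit <- loglog_diagnostic(curve, n_segments = 2)
  expect_equal(fit$exponents[1], 1, tolerance = 0.05)
  expect_equal(fit$exponents[2], 0.6, tolerance = 0.05)
  expect_equal(fit$breakpoints, 1, tolerance = 0.35)
  # continuity of the fitted line at the knot
  lk <- log(fit$breakpoints)
  left <- fit$fitted_loglog(lk - 1e-9)
  right <- fit$fitted_loglog(lk + 1e-9)
  expect_equal(left, right, tolerance = 1e-6)
})

test_that("reflected-Wiener walks show the two normal-diffusion plateaus", {
  # early window: free diffusion at ln(6 D0)
  early <- simulate_wiener(walk_config("wiener", rho = 0.6, n_walks = 3000,
                                       t_max = 0.25, seed = 81))
  f_early <- fit_de(early)
  expect_equal(log(f_early$slope), log(6), tolerance = 0.05)
  # late window: hindered normal diffusion at ln(6 De) < ln(6 D0)
  late <- simulate_wiener(walk_config("wiener", rho = 0.6, n_walks = 3000,
                                      seed = 82))
  f_late <- fit_de(late, fit_range = c(33, 67))
  expect_lt(log(f_late$slope), log(6))
  expect_gt(f_late$De, 0.8)   # hindrance is mild at rho = 0.6
})
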