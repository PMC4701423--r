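# Scripted reference experiments: each target re-runs one headline
# computation end to end (sweep + exponential fit; overlap concentration;
# small-t Wiener asymptote; Monte Carlo CI tightness) and reports the
# resulting number.  scripts/acceptance.R and the command-line `reproduce`
# subcommand are thin wrappers around this.

#' Re-run a scripted reference experiment
#'
#' Available targets:
#' \describe{
#'   \item{t1}{least-squares exponent `k` of `exp(-k rho^3)` fitted to the
#'     homogenization sweep over `rho = 0, 0.04, ..., 0.92`.}
#'   \item{t2}{maximum absolute deviation between that fitted law and the
#'     sweep over the same domain.}
#'   \item{t3}{geometric overlap concentration of Dextran70 (% w/v, one
#'     decimal).}
#'   \item{t4}{small-time plateau of `ln(MSD(t)/t)` for the reflected
#'     Wiener walk at `rho = 0.6` (expected `ln 6` since `D0 = 1`),
#'     estimated from an ensemble over a window short enough that
#'     essentially no walker has reached an obstruction.}
#'   \item{t5}{95% CI width of the kinetic-model `De` estimate at
#'     `rho = 0.6`, as a percentage of the estimate, extrapolated from
#'     `N = 10^4` walks to `N = 10^5` by `1/sqrt(N)` scaling.}
#' }
#'
#' @param id target id (`"t1"` ... `"t5"`).
#' @param seed integer seed for the stochastic targets.
#' @param n_grid base grid resolution of the homogenization sweep
#'   (Richardson-extrapolated against `2 n_grid`).
#' @param n_walks ensemble size for the Monte Carlo targets.
#' @return A list with elements `value` and `n` (problem size used).
#' @export
reproduce_target <- function(id, seed = 1L, n_grid = 64L, n_walks = 10000L) {
  id <- as.character(id)
  seed <- as.integer(seed)
  switch(id,
    t1 = ,
    t2 = {
      rhos <- seq(0, 0.92, by = 0.04)
      sweep <- homogenization_sweep(rhos, n = n_grid)
      fit <- fit_k(sweep, rho_max = 0.92)
      if (id == "t1") list(value = fit$k, n = length(rhos))
      else list(value = fit$max_abs_error, n = length(rhos))
    },
    t3 = {
      dex70 <- polymer_library()$polymers$dextran70
      list(value = round(geometric_overlap_concentration(dex70), 1), n = 1L)
    },
    t4 = {
      # window chosen so the RMS free displacement stays ~4 sigma short of
      # the nearest obstruction surface: collisions are negligible
      cfg <- walk_config("wiener", rho = 0.6, L = 5, D0 = 1,
                         n_walks = n_walks, n_record = 250, t_max = 0.25,
                         init = "midpoint", seed = seed)
      ens <- simulate_wiener(cfg)
      list(value = log(fit_de(ens)$slope), n = n_walks)
    },
    t5 = {
      cfg <- walk_config("kinetic", rho = 0.6, L = 5, D0 = 1,
                         n_walks = n_walks, init = "midpoint", seed = seed)
      est <- fit_de(simulate_kinetic(cfg))
      rel_width <- 100 * diff(est$ci95) / est$De
      list(value = rel_width * sqrt(n_walks / 1e5), n = n_walks)
    },
    stop(sprintf("unknown target '%s'", id), call. = FALSE)
  )
}
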