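# Monte Carlo module: obstructed random walks among periodic impenetrable
# spheres under two microscopic models.  The walkers themselves run in
# compiled code (src/walkers.cpp) on per-walk counter-seeded RNG streams.

# surface-to-surface gap controlling the Euler step-size rule: along the
# lattice axis for rho < 1, across the face-diagonal channel above
.void_gap <- function(rho, L) {
  if (rho < 1) L * (1 - rho) else L * (sqrt(2) - rho)
}

#' Configuration of an obstructed-random-walk ensemble
#'
#' Collects every parameter of a simulation: the microscopic model, the
#' obstruction geometry, the time discretization and the RNG seed.
#'
#' Defaults mirror the reference study conditions: spacing `L = 5`
#' (length scale of nm), free diffusivity `D0 = 1` (time scale chosen so
#' free diffusion is unity), kinetic mean free path `lambda = 0.2` (the
#' mean free path of a water molecule in water, in nm) with mean step
#' duration `tau = lambda^2 / (3 D0)` so that the unobstructed kinetic walk
#' reproduces `D0`, and 250 positions recorded at equidistant times.  The
#' default horizon `t_max = (4 L)^2 / (6 D0)` lets the RMS displacement
#' traverse about four cells, well past the free-to-hindered transition.
#' The default Euler step satisfies `sqrt(6 D0 dt) <= gap/10`, where `gap`
#' is the narrowest void passage.
#'
#' @param model `"wiener"` (Euler-discretized reflected Brownian motion)
#'   or `"kinetic"` (rectilinear flights with i.i.d. exponential lengths
#'   and durations and isotropic directions).
#' @param rho obstruction parameter (obstruction diameter over spacing);
#'   values up to 2 are accepted, with a warning above `sqrt(2)` where the
#'   void disconnects.
#' @param L lattice spacing (simulation length units).
#' @param D0 free diffusivity.
#' @param lambda,tau kinetic-model mean free path and mean step duration.
#' @param n_walks number of independent walkers.
#' @param n_record number of equidistant recording times (first is t = 0).
#' @param t_max time horizon.
#' @param dt Euler time step (Wiener model); default from the gap rule.
#' @param init `"midpoint"` starts every walk at the cell body-center
#'   (equidistant from the 8 nearest obstructions); `"uniform"` samples
#'   uniformly over the accessible void.
#' @param seed non-negative integer seed; ensembles are reproducible and
#'   walker-order independent.
#' @param max_reflect cap on reflections resolved within one step.
#' @return An object of class `"walk_config"`.
#' @export
#' @examples
#' walk_config("wiener", rho = 0.6, n_walks = 1000, seed = 7)
walk_config <- function(model = c("wiener", "kinetic"), rho, L = 5, D0 = 1,
                        lambda = 0.2, tau = lambda^2 / (3 * D0),
                        n_walks = 100000L, n_record = 250L, t_max = NULL,
                        dt = NULL, init = c("midpoint", "uniform"),
                        seed = 1L, max_reflect = 1000L) {
  model <- match.arg(model)
  init <- match.arg(init)
  if (!is.finite(rho) || rho < 0 || rho >= 2)
    stop("'rho' must be in [0, 2)", call. = FALSE)
  .check_positive(L, "L"); .check_positive(D0, "D0")
  .check_positive(lambda, "lambda"); .check_positive(tau, "tau")
  if (n_walks < 1 || n_record < 2) stop("need n_walks >= 1, n_record >= 2",
                                        call. = FALSE)
  if (rho >= sqrt(2))
    warning("rho >= sqrt(2): void is disconnected; walkers stay caged")
  gap <- .void_gap(rho, L)
  if (is.null(t_max)) t_max <- (4 * L)^2 / (6 * D0)
  .check_positive(t_max, "t_max")
  if (model == "wiener") {
    dt_max <- if (gap > 0) (gap / 10)^2 / (6 * D0) else NA_real_
    if (is.null(dt)) {
      if (!is.finite(dt_max))
        stop("no connected void: supply 'dt' explicitly", call. = FALSE)
      dt <- dt_max
    }
    .check_positive(dt, "dt")
    if (is.finite(dt_max) && dt > dt_max * (1 + 1e-9))
      stop(sprintf(paste0("dt = %.3g too large: the RMS Euler step must not ",
                          "exceed a tenth of the void gap (dt <= %.3g)"),
                   dt, dt_max), call. = FALSE)
  }
  structure(list(model = model, rho = rho, L = L, D0 = D0, lambda = lambda,
                 tau = tau, n_walks = as.integer(n_walks),
                 n_record = as.integer(n_record), t_max = t_max, dt = dt,
                 init = init, seed = as.numeric(seed),
                 max_reflect = as.integer(max_reflect)),
            class = "walk_config")
}

#' @export
print.walk_config <- function(x, ...) {
  cat(sprintf("<walk_config> %s: rho = %g, L = %g, D0 = %g, N = %d, t_max = %.3g, init = %s, seed = %g\n",
              x$model, x$rho, x$L, x$D0, x$n_walks, x$t_max, x$init, x$seed))
  if (x$model == "wiener") cat(sprintf("  dt = %.4g\n", x$dt))
  else cat(sprintf("  lambda = %g, tau = %.5g\n", x$lambda, x$tau))
  invisible(x)
}

.as_ensemble <- function(raw, config, record_positions) {
  ens <- structure(list(config = config, times = raw$times,
                        sq_disp = raw$sq_disp,
                        dt_used = raw$dt_used %||% NULL),
                   class = "ensemble_record")
  if (record_positions) ens$positions <- raw$positions
  ens
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the reflected Wiener process
#'
#' Euler-Maruyama discretization of Brownian motion with free diffusivity
#' `D0`: each walker advances by Gaussian increments of per-axis variance
#' `2 D0 dt`; a step whose endpoint lands inside an obstruction is resolved
#' by specular reflection of the residual sub-segment about the sphere
#' surface, iterated as needed.
#'
#' @param config a [walk_config()] with `model = "wiener"`.
#' @param record_positions also keep every recorded position (3 x n_record
#'   x n_walks array); memory-hungry for large ensembles.
#' @return An object of class `"ensemble_record"`: `config`, `times`
#'   (length `n_record`, starting at 0), `sq_disp` (n_walks x n_record
#'   matrix of squared displacements), `dt_used`, and optionally
#'   `positions`.
#' @export
#' @examples
#' ens <- simulate_wiener(walk_config("wiener", rho = 0, n_walks = 50,
#'                                    t_max = 1, n_record = 10, seed = 1))
simulate_wiener <- function(config, record_positions = FALSE) {
  stopifnot(inherits(config, "walk_config"), config$model == "wiener")
  raw <- simulate_wiener_cpp(config$rho, config$L, config$D0, config$n_walks,
                             config$n_record, config$t_max, config$dt,
                             match(config$init, c("midpoint", "uniform")) - 1L,
                             config$seed, config$max_reflect, record_positions)
  .as_ensemble(raw, config, record_positions)
}

#' Simulate the kinetic (velocity-jump) model
#'
#' Rectilinear flights with i.i.d. exponential path lengths (mean
#' `lambda`), i.i.d. exponential durations (mean `tau`) and directions
#' uniform on the sphere; specular reflection at obstruction surfaces
#' continues the remaining path length.  The duration of a step is consumed
#' uniformly along its (possibly reflected) path, so recorded times falling
#' inside a step are interpolated on the polyline.  Unobstructed, the walk
#' has `MSD(t) -> (2 lambda^2 / tau) t` for large `t`; the default
#' `tau = lambda^2 / (3 D0)` therefore reproduces free diffusivity `D0`.
#'
#' @param config a [walk_config()] with `model = "kinetic"`.
#' @inheritParams simulate_wiener
#' @return An `"ensemble_record"`; see [simulate_wiener()].
#' @export
simulate_kinetic <- function(config, record_positions = FALSE) {
  stopifnot(inherits(config, "walk_config"), config$model == "kinetic")
  raw <- simulate_kinetic_cpp(config$rho, config$L, config$D0, config$lambda,
                              config$tau, config$n_walks, config$n_record,
                              config$t_max,
                              match(config$init, c("midpoint", "uniform")) - 1L,
                              config$seed, config$max_reflect,
                              record_positions)
  .as_ensemble(raw, config, record_positions)
}

#' Simulate an ensemble under either model
#'
#' Dispatches on `config$model`.
#'
#' @inheritParams simulate_wiener
#' @export
simulate_ensemble <- function(config, record_positions = FALSE) {
  if (config$model == "wiener") simulate_wiener(config, record_positions)
  else simulate_kinetic(config, record_positions)
}

#' @export
print.ensemble_record <- function(x, ...) {
  cat(sprintf("<ensemble_record> %s model, %d walks x %d times (t in [0, %.3g]), rho = %g\n",
              x$config$model, nrow(x$sq_disp), ncol(x$sq_disp),
              max(x$times), x$config$rho))
  invisible(x)
}

#' Resolve a segment with specular reflections
#'
#' Follows `start + displacement` through the periodic sphere lattice,
#' reflecting specularly at any obstruction surface hit and preserving the
#' total path length.  Tangent (grazing) contact counts as no collision.
#' Exposed mainly for validation; the simulators use the same compiled
#' routine internally.
#'
#' @param start length-3 numeric, strictly outside all obstructions.
#' @param displacement length-3 numeric step vector.
#' @param rho,L obstruction parameter and lattice spacing (obstruction
#'   radius `rho * L / 2`).
#' @param max_reflect reflection cap.
#' @return Length-3 numeric endpoint, outside all obstructions.
#' @export
#' @examples
#' reflect_segment(c(2.5, 2.5, 2.5), c(0.5, 0, 0), rho = 0.6, L = 5)
reflect_segment <- function(start, displacement, rho, L = 5,
                            max_reflect = 1000L) {
  stopifnot(length(start) == 3, length(displacement) == 3)
  reflect_segment_cpp(as.numeric(start), as.numeric(displacement),
                      rho * L / 2, L, as.integer(max_reflect))
}

#' Initial position of a walker
#'
#' `"midpoint"` returns the body-center of the cubic cell, at distance
#' \eqn{L\sqrt{3}/2} from the eight nearest obstruction centers;
#' `"uniform"` rejection-samples uniformly over the cell until the point
#' falls outside every obstruction (acceptance probability \eqn{1-\phi}).
#' Uses R's RNG stream (the compiled simulators draw their own starts from
#' per-walk streams).
#'
#' @param config a [walk_config()].
#' @param max_tries rejection-sampling budget.
#' @return Length-3 numeric position.
#' @export
initial_position <- function(config, max_tries = 100000L) {
  stopifnot(inherits(config, "walk_config"))
  L <- config$L
  if (config$init == "midpoint") return(rep(L / 2, 3))
  r2 <- (config$rho * L / 2)^2
  for (i in seq_len(max_tries)) {
    p <- runif(3, 0, L)
    d <- p - L * round(p / L)
    if (sum(d^2) >= r2) return(p)
  }
  stop("could not sample an unobstructed point (void fraction too small)",
       call. = FALSE)
}

# post-hoc invariant check used by tests: no recorded position inside any
# obstruction sphere
.positions_clear <- function(ens, tol = 1e-9) {
  stopifnot(!is.null(ens$positions))
  L <- ens$config$L
  r <- ens$config$rho * L / 2
  p <- matrix(ens$positions, nrow = 3)
  d <- p - L * round(p / L)
  all(colSums(d^2) >= r^2 * (1 - tol) - tol)
}
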