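# FCS module: single-component autocorrelation model for normal diffusion
# through a 3-D Gaussian confocal volume, nonlinear fitting, conversions
# between diffusion time and diffusivity, and a synthetic-curve generator.

#' FCS autocorrelation model (single component, normal diffusion)
#'
#' \deqn{G(\tau) = 1 + \frac{1}{N}\,\frac{1}{1+\tau/\tau_d}\,
#'   \frac{1}{\sqrt{1 + p\,\tau/\tau_d}}}
#' where `N` is the mean particle number in the confocal volume, `tau_d`
#' the characteristic diffusion time and `p = (r0/z0)^2` the instrumental
#' structure constant.
#'
#' @param tau delay time(s) (s), `> 0` (vectorized).
#' @param n mean occupancy `N`, `> 0`.
#' @param tau_d diffusion time (s), `> 0`.
#' @param p structure constant, `> 0` (typically well below 1).
#' @return Autocorrelation amplitude(s).
#' @export
#' @examples
#' fcs_model(3.9e-5, n = 5, tau_d = 3.9e-5, p = 0.04)
fcs_model <- function(tau, n, tau_d, p) {
  .check_positive(n, "n"); .check_positive(tau_d, "tau_d")
  .check_positive(p, "p")
  1 + (1 / n) / ((1 + tau / tau_d) * sqrt(1 + p * tau / tau_d))
}

#' FCS curve container
#'
#' @param delays strictly increasing positive delay times (s).
#' @param g autocorrelation amplitudes.
#' @return A data frame of class `"fcs_curve"` with columns `delay_s`, `G`.
#' @export
fcs_curve <- function(delays, g) {
  if (length(delays) != length(g)) stop("length mismatch", call. = FALSE)
  if (any(delays <= 0) || is.unsorted(delays, strictly = TRUE))
    stop("'delays' must be strictly increasing and positive", call. = FALSE)
  if (any(!is.finite(g))) stop("'g' must be finite", call. = FALSE)
  out <- data.frame(delay_s = delays, G = g)
  class(out) <- c("fcs_curve", "data.frame")
  out
}

#' Read / write FCS curves as two-column CSV
#'
#' Files have columns `delay_s` (seconds) and `G`.
#'
#' @param path file path.
#' @return [read_fcs()] returns an `"fcs_curve"`; [write_fcs()] returns
#'   `path` invisibly.
#' @export
read_fcs <- function(path) {
  df <- read.csv(path)
  if (!all(c("delay_s", "G") %in% names(df)))
    stop("expected columns 'delay_s' and 'G'", call. = FALSE)
  fcs_curve(df$delay_s, df$G)
}

#' @rdname read_fcs
#' @param curve an `"fcs_curve"`.
#' @export
write_fcs <- function(curve, path) {
  stopifnot(inherits(curve, "fcs_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Fit the FCS model to an autocorrelation curve
#'
#' Nonlinear least squares for `(N, tau_d)` with the structure constant
#' `p` held fixed, as is standard when `p` is calibrated once per
#' instrument.  Initial guesses: `N` from the zero-delay amplitude
#' `1/(G(tau_min) - 1)` and `tau_d` from the delay nearest the half-decay
#' of `G - 1`.
#'
#' @param curve an `"fcs_curve"` (or data frame with `delay_s`, `G`),
#'   at least 10 points spanning the decay.
#' @param p fixed structure constant `(r0/z0)^2`.  The default 0.04 is a
#'   typical confocal geometry (an axial-to-radial aspect of 5), not an
#'   instrument-specific calibration; supply your own whenever known.
#' @return An object of class `"fcs_fit"`: `n_particles`, `tau_d`, `p`,
#'   `residual_ss`, `r_squared`, and the underlying `fit` object.
#' @export
#' @examples
#' cv <- synthesize_fcs(n = 5, tau_d = 5e-5, p = 0.04,
#'                      delays = 10^seq(-6, -1, length.out = 60))
#' fit_fcs(cv, p = 0.04)
fit_fcs <- function(curve, p = 0.04) {
  stopifnot(is.data.frame(curve), all(c("delay_s", "G") %in% names(curve)))
  .check_positive(p, "p")
  if (nrow(curve) < 10)
    stop("need at least 10 points spanning the decay", call. = FALSE)
  tau <- curve$delay_s
  g <- curve$G
  g0 <- max(g[1] - 1, 1e-6)
  n0 <- 1 / g0
  half <- 1 + g0 / 2
  tau_d0 <- tau[which.min(abs(g - half))]
  df <- data.frame(tau = tau, g = g)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ 1 + (1 / N) / ((1 + tau / tau_d) * sqrt(1 + p * tau / tau_d)),
      data = df, start = list(N = n0, tau_d = tau_d0),
      lower = c(N = 1e-12, tau_d = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf(paste0("FCS fit did not converge (start N = %.3g, ",
                          "tau_d = %.3g): %s"), n0, tau_d0,
                   conditionMessage(e)), call. = FALSE))
  est <- coef(fit)
  pred <- fcs_model(tau, est[["N"]], est[["tau_d"]], p)
  structure(list(n_particles = est[["N"]], tau_d = est[["tau_d"]], p = p,
                 residual_ss = sum((g - pred)^2),
                 r_squared = r_squared(g, pred), fit = fit),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("<fcs_fit> N = %.4g, tau_d = %.4g s (p fixed at %.3g), R^2 = %.4f\n",
              x$n_particles, x$tau_d, x$p, x$r_squared))
  invisible(x)
}

#' Convert a diffusion time to a diffusivity (and back)
#'
#' For a 3-D Gaussian beam of radial waist `r0`,
#' \eqn{\tau_d = r_0^2 / (4D)}.
#'
#' @param tau_d diffusion time (s).
#' @param r0 radial beam waist (nm); 208 nm is a typical calibrated value.
#' @return Diffusivity in m^2/s.
#' @export
#' @examples
#' diffusion_time_to_diffusivity(3.86e-5, r0 = 208)
diffusion_time_to_diffusivity <- function(tau_d, r0 = 208) {
  .check_positive(tau_d, "tau_d"); .check_positive(r0, "r0")
  (r0 * 1e-9)^2 / (4 * tau_d)
}

#' @rdname diffusion_time_to_diffusivity
#' @param D diffusivity (m^2/s).
#' @export
diffusivity_to_diffusion_time <- function(D, r0 = 208) {
  .check_positive(D, "D"); .check_positive(r0, "r0")
  (r0 * 1e-9)^2 / (4 * D)
}

#' Normalized effective diffusivity from diffusion times
#'
#' The experimental \eqn{D_e/D_0} is the ratio of the free-solution
#' diffusion time to the in-solution diffusion time,
#' \eqn{\tau_0/\tau_d}.  Warns when the ratio exceeds 1, which obstruction
#' alone cannot produce.
#'
#' @param tau_0 free-solution diffusion time (s).
#' @param tau_d diffusion time in the polymer solution (s).
#' @return \eqn{D_e/D_0}.
#' @export
normalized_diffusivity <- function(tau_0, tau_d) {
  .check_positive(tau_0, "tau_0"); .check_positive(tau_d, "tau_d")
  val <- tau_0 / tau_d
  if (any(val > 1 + 1e-9))
    warning("normalized diffusivity exceeds 1: faster than free diffusion")
  val
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares about
#' the observed mean.  May be negative for a worse-than-mean predictor.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 2).
#' @return \eqn{R^2 \le 1}.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("need equal-length vectors with at least 2 values", call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("constant observations: R^2 undefined", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Synthesize an FCS autocorrelation curve
#'
#' Evaluates the single-component model on a delay grid and adds zero-mean
#' Gaussian noise; reproducible from `seed` without disturbing the global
#' RNG state.
#'
#' @inheritParams fcs_model
#' @param delays strictly increasing positive delay grid (s).
#' @param noise_sd standard deviation of the additive amplitude noise.
#' @param seed optional integer seed.
#' @return An `"fcs_curve"`.
#' @export
synthesize_fcs <- function(n, tau_d, p, delays, noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  g <- fcs_model(delays, n, tau_d, p)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    g <- g + rnorm(length(delays), 0, noise_sd)
  }
  fcs_curve(delays, g)
}
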