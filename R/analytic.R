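# Analytic module: closed-form comparator models for De/D0 and the
# exponential-law fit to the homogenization curve.

#' Exponential law for the normalized effective diffusivity
#'
#' \eqn{D_e/D_0 = e^{-k\rho^3}}: a one-parameter closed form that tracks
#' the homogenization curve closely for moderate obstruction.
#'
#' @param rho obstruction parameter(s), `>= 0`.
#' @param k positive rate constant; see [fit_k()].
#' @return \eqn{D_e/D_0} values.
#' @export
#' @examples
#' exp_formula(0.92, 0.2568)
exp_formula <- function(rho, k) {
  if (any(rho < 0)) stop("'rho' must be >= 0", call. = FALSE)
  .check_positive(k, "k")
  exp(-k * rho^3)
}

#' Fit the exponential law to a model curve
#'
#' Least-squares (default) or minimax fit of \eqn{e^{-k\rho^3}} to a
#' \eqn{D_e/D_0} curve over \eqn{\rho \le \rho_{max}}, reporting the
#' maximum absolute deviation over the fitted domain.
#'
#' @param curve a `"model_curve"` (e.g. from [homogenization_sweep()]) or a
#'   data frame with columns `rho` and `De_over_D0`.
#' @param rho_max upper end of the fit domain.
#' @param method `"ls"` (sum of squared errors) or `"minimax"` (maximum
#'   absolute error).
#' @return An object of class `"exp_fit"`: `k`, `rho_max`,
#'   `max_abs_error`, `method`.
#' @export
fit_k <- function(curve, rho_max = 0.92, method = c("ls", "minimax")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(curve), all(c("rho", "De_over_D0") %in% names(curve)))
  keep <- curve$rho <= rho_max + 1e-12
  if (sum(keep) < 5)
    stop("need at least 5 curve points with rho <= rho_max", call. = FALSE)
  r3 <- curve$rho[keep]^3
  de <- curve$De_over_D0[keep]
  obj <- if (method == "ls") {
    function(k) sum((de - exp(-k * r3))^2)
  } else {
    function(k) max(abs(de - exp(-k * r3)))
  }
  k <- optimize(obj, interval = c(1e-4, 5), tol = 1e-10)$minimum
  structure(list(k = k, rho_max = rho_max,
                 max_abs_error = max(abs(de - exp(-k * r3))),
                 method = method),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> De/D0 = exp(-k rho^3), k = %.4f (%s fit on rho <= %g), max |error| = %.2e\n",
              x$k, x$method, x$rho_max, x$max_abs_error))
  invisible(x)
}

#' Maxwell's effective-medium formula
#'
#' Classical dilute-inclusion result for spheres of interior-to-exterior
#' diffusivity ratio \eqn{\delta} embedded in a continuum:
#' \deqn{D_e/D_0 = \frac{1 - \Lambda\rho^3/12}{1 + \Lambda\rho^3/24},
#'   \quad \Lambda = \frac{4\pi(1-\delta)}{2+\delta}.}
#' Impenetrable obstacles correspond to \eqn{\delta = 0}
#' (\eqn{\Lambda = 2\pi}).  The internal symbol `L_maxwell` is distinct
#' from the lattice spacing `L`.
#'
#' @param rho obstruction parameter(s), `>= 0`.
#' @param delta interior-to-exterior diffusivity ratio, `>= 0`.
#' @return \eqn{D_e/D_0}; warns when the formula breaks down
#'   (non-positive value at large \eqn{\rho}).
#' @export
#' @examples
#' maxwell_formula(1)          # 0.3776 for impenetrable spheres
maxwell_formula <- function(rho, delta = 0) {
  if (any(rho < 0)) stop("'rho' must be >= 0", call. = FALSE)
  if (any(delta < 0)) stop("'delta' must be >= 0", call. = FALSE)
  L_maxwell <- 4 * pi * (1 - delta) / (2 + delta)
  val <- (1 - L_maxwell * rho^3 / 12) / (1 + L_maxwell * rho^3 / 24)
  if (any(val <= 0))
    warning("Maxwell formula non-positive: outside its domain of validity")
  val
}

#' Volume-fraction-scaled Maxwell formula
#'
#' Maxwell's impenetrable-sphere formula divided by the accessible volume
#' fraction \eqn{1 - \phi}; this conversion between the two effective-
#' diffusivity conventions brings the classical formula into close
#' agreement with the homogenization curve for \eqn{\rho \le 1}.
#'
#' @inheritParams exp_formula
#' @return \eqn{D_e/D_0} values.
#' @export
scaled_maxwell <- function(rho) {
  maxwell_formula(rho, delta = 0) / (1 - obstructed_fraction(rho))
}

#' Accessible-volume-fraction (naive) average
#'
#' The straightforward spatial average of the fine-scale diffusivity:
#' \eqn{1 - \phi(\rho)}.  Systematically below the homogenization
#' prediction — obstructed diffusion is not a simple volume average.
#'
#' @inheritParams exp_formula
#' @return \eqn{1 - \phi} values.
#' @export
naive_average <- function(rho) {
  1 - obstructed_fraction(rho)
}

#' Tabulate all comparator models over a rho grid
#'
#' @param rho ascending grid of obstruction parameters (`< sqrt(2)`).
#' @param homogenization optional `"model_curve"` to interpolate alongside
#'   the closed forms (monotone cubic interpolation).
#' @param k rate for the exponential law.
#' @return A data frame with one column per model.
#' @export
compare_models <- function(rho, homogenization = NULL, k = 0.2568) {
  out <- data.frame(rho = rho,
                    exp_formula = exp_formula(rho, k),
                    maxwell = maxwell_formula(rho),
                    scaled_maxwell = scaled_maxwell(rho),
                    naive = naive_average(rho))
  if (!is.null(homogenization)) {
    f <- splinefun(homogenization$rho, homogenization$De_over_D0,
                   method = "monoH.FC")
    out$homogenization <- f(rho)
  }
  out
}
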