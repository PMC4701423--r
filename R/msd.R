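# MSD module: ensemble-mean squared displacement, through-origin slope
# fitting with uncertainty, and anomalous-vs-normal diffusion diagnostics.

#' Estimate the mean squared displacement of an ensemble
#'
#' Sample mean of the per-walk squared displacements at each recorded time,
#' with the standard error of that mean.
#'
#' @param ensemble an `"ensemble_record"` from [simulate_wiener()] or
#'   [simulate_kinetic()].
#' @return An object of class `"msd_curve"`: a data frame with columns
#'   `time`, `msd`, `stderr`, and attribute `n_walks`.
#' @export
estimate_msd <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_record"))
  sq <- ensemble$sq_disp
  n <- nrow(sq)
  if (is.null(sq) || n < 2) stop("ensemble must hold at least 2 walks",
                                 call. = FALSE)
  m <- colMeans(sq)
  v <- colMeans(sq^2) - m^2
  v <- pmax(v, 0) * n / (n - 1)
  out <- data.frame(time = ensemble$times, msd = m, stderr = sqrt(v / n))
  class(out) <- c("msd_curve", "data.frame")
  attr(out, "n_walks") <- n
  out
}

.resolve_fit_range <- function(times, fit_range) {
  if (is.null(fit_range)) fit_range <- range(times)
  stopifnot(length(fit_range) == 2)
  keep <- times >= fit_range[1] & times <= fit_range[2]
  if (sum(keep & times > 0) < 3)
    stop("need at least 3 recorded times with t > 0 in the fit range",
         call. = FALSE)
  keep
}

#' Effective diffusivity from the MSD slope
#'
#' Fits the least-squares line through the origin to MSD versus time and
#' estimates \eqn{D_e} = slope / 6 (3-D).  Called on an ensemble, the same
#' through-origin fit is applied to every individual walk and the 95%
#' confidence interval is `mean +/- 1.96 sd / sqrt(N)` of the per-walk
#' slopes (whose mean is exactly the ensemble slope); `ci = "bootstrap"`
#' resamples walks instead.  Called on a bare `"msd_curve"` the per-walk
#' information is gone and a wider t-based interval from the weighted
#' residuals is returned with a warning.
#'
#' @param x an `"ensemble_record"` or an `"msd_curve"`.
#' @param fit_range length-2 time window (default: full recorded window;
#'   use `c(t_max/2, t_max)` to restrict to the linear tail, avoiding the
#'   slight upward bias from the early free-diffusion transient).
#' @param ci `"perwalk"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap replicates.
#' @param ... unused.
#' @return An object of class `"diffusivity_estimate"`: `slope`, `De`,
#'   `ci95` (length-2), `se`, `fit_range`, `n_walks`.
#' @export
fit_de <- function(x, ...) UseMethod("fit_de")

#' @rdname fit_de
#' @export
fit_de.ensemble_record <- function(x, fit_range = NULL,
                                   ci = c("perwalk", "bootstrap"),
                                   n_boot = 200L, ...) {
  ci <- match.arg(ci)
  t <- x$times
  keep <- .resolve_fit_range(t, fit_range)
  tt <- t[keep]
  sq <- x$sq_disp[, keep, drop = FALSE]
  n <- nrow(sq)
  denom <- sum(tt^2)
  if (denom == 0) stop("degenerate fit range", call. = FALSE)
  slopes <- as.numeric(sq %*% tt) / denom   # per-walk through-origin slopes
  slope <- mean(slopes)
  if (all(sq == 0)) stop("all-zero MSD curve: nothing to fit", call. = FALSE)
  if (n < 30)
    warning("fewer than 30 walks: normal-approximation CI is unreliable")
  se_slope <- if (ci == "perwalk") {
    sd(slopes) / sqrt(n)
  } else {
    bs <- replicate(n_boot, mean(slopes[sample.int(n, n, replace = TRUE)]))
    sd(bs)
  }
  de <- slope / 6
  se <- se_slope / 6
  structure(list(slope = slope, De = de,
                 ci95 = c(de - 1.96 * se, de + 1.96 * se), se = se,
                 fit_range = range(tt), n_walks = n, ci_method = ci),
            class = "diffusivity_estimate")
}

#' @rdname fit_de
#' @export
fit_de.msd_curve <- function(x, fit_range = NULL, ...) {
  keep <- .resolve_fit_range(x$time, fit_range)
  tt <- x$time[keep]
  mm <- x$msd[keep]
  if (all(mm == 0)) stop("all-zero MSD curve: nothing to fit", call. = FALSE)
  slope <- sum(tt * mm) / sum(tt^2)
  # t-based fallback interval from the regression residuals
  res <- mm - slope * tt
  k <- length(tt)
  se_slope <- sqrt(sum(res^2) / (k - 1) / sum(tt^2))
  warning("per-walk data unavailable: returning a wider t-based interval")
  de <- slope / 6
  se <- se_slope / 6
  q <- qt(0.975, df = k - 1)
  structure(list(slope = slope, De = de, ci95 = c(de - q * se, de + q * se),
                 se = se, fit_range = range(tt),
                 n_walks = attr(x, "n_walks") %||% NA_integer_,
                 ci_method = "t-based"),
            class = "diffusivity_estimate")
}

#' 95% confidence interval for the through-origin MSD slope
#'
#' Convenience wrapper around [fit_de()] returning just the interval for
#' \eqn{D_e}.
#'
#' @inheritParams fit_de.ensemble_record
#' @param ensemble an `"ensemble_record"`.
#' @return Length-2 numeric interval.
#' @export
confidence_interval <- function(ensemble, fit_range = NULL,
                                ci = c("perwalk", "bootstrap")) {
  fit_de(ensemble, fit_range = fit_range, ci = ci)$ci95
}

#' @export
print.diffusivity_estimate <- function(x, ...) {
  cat(sprintf("<diffusivity_estimate> De = %.5f (95%% CI %.5f - %.5f, %s, N = %s)\n",
              x$De, x$ci95[1], x$ci95[2], x$ci_method, x$n_walks))
  invisible(x)
}

#' Log-log anomalous-diffusion diagnostic
#'
#' Fits a continuous piecewise-linear model to \eqn{\ln(MSD(t)/t)} versus
#' \eqn{\ln t} (natural logarithms).  On a segment where
#' \eqn{MSD = C_i t^{\alpha_i}} the plot is linear with slope
#' \eqn{\alpha_i - 1} and intercept \eqn{\ln C_i}; normal diffusion gives a
#' flat segment at \eqn{\ln(6 D)}.  Breakpoints are chosen by exhaustive
#' search over a quantile grid of candidate knots, minimizing the sum of
#' squared errors with continuity enforced through a truncated-power basis.
#'
#' @param curve an `"msd_curve"` with strictly positive `msd` for `t > 0`.
#' @param n_segments number of power-law segments (1 = single power law).
#' @param n_knot_grid number of candidate knot positions.
#' @return An object of class `"anomalous_fit"`: `breakpoints` (times,
#'   length `n_segments - 1`), `exponents` (\eqn{\alpha_i}), `intercepts`
#'   (\eqn{C_i}), `sse`, and `fitted_loglog` (function of \eqn{\ln t}).
#' @export
loglog_diagnostic <- function(curve, n_segments = 1L, n_knot_grid = 30L) {
  stopifnot(inherits(curve, "msd_curve"))
  pos <- curve$time > 0
  t <- curve$time[pos]
  m <- curve$msd[pos]
  if (any(m <= 0))
    stop("msd must be strictly positive for t > 0", call. = FALSE)
  if (length(t) < 2L * n_segments)
    stop("fewer points than 2 x segments", call. = FALSE)
  u <- log(t)
  v <- log(m / t)
  fit_with_knots <- function(knots) {
    X <- cbind(1, u)
    for (k in knots) X <- cbind(X, pmax(u - k, 0))
    f <- lm.fit(X, v)
    list(coef = f$coefficients, sse = sum(f$residuals^2))
  }
  if (n_segments == 1L) {
    best <- fit_with_knots(numeric(0))
    knots <- numeric(0)
  } else {
    cand <- unique(quantile(u, probs = seq(0.05, 0.95,
                                           length.out = n_knot_grid),
                            names = FALSE))
    combs <- utils::combn(cand, n_segments - 1L, simplify = FALSE)
    fits <- lapply(combs, fit_with_knots)
    i <- which.min(vapply(fits, `[[`, 0, "sse"))
    best <- fits[[i]]
    knots <- combs[[i]]
  }
  b <- best$coef
  slopes <- cumsum(c(b[2], if (length(knots)) b[-(1:2)]))
  # segment intercepts chained through the continuity constraints
  icepts <- numeric(length(slopes))
  icepts[1] <- b[1]
  if (length(knots))
    for (s in seq_along(knots))
      icepts[s + 1] <- icepts[s] + (slopes[s] - slopes[s + 1]) * knots[s]
  structure(list(breakpoints = exp(knots), exponents = unname(slopes + 1),
                 intercepts = unname(exp(icepts)), sse = best$sse,
                 fitted_loglog = function(lu) {
                   y <- b[1] + b[2] * lu
                   for (s in seq_along(knots))
                     y <- y + b[2 + s] * pmax(lu - knots[s], 0)
                   y
                 }),
            class = "anomalous_fit")
}

#' @export
print.anomalous_fit <- function(x, ...) {
  cat(sprintf("<anomalous_fit> %d segment(s)\n", length(x$exponents)))
  cat("  exponents alpha:", paste(sprintf("%.3f", x$exponents), collapse = ", "), "\n")
  cat("  amplitudes C:   ", paste(sprintf("%.3f", x$intercepts), collapse = ", "), "\n")
  if (length(x$breakpoints))
    cat("  breakpoints t:  ", paste(sprintf("%.3g", x$breakpoints), collapse = ", "), "\n")
  invisible(x)
}
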