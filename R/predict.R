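# Workflow module: concentration-series prediction tables tying geometry,
# homogenization and the comparators together.

#' Predict normalized diffusivity over a concentration series
#'
#' For each concentration: the lattice spacing `L`, the obstruction
#' parameter `rho`, and `De/D0` interpolated (monotone cubic) from a
#' homogenization sweep.  Concentrations above the geometric overlap
#' concentration \eqn{c^\theta} are flagged: there the rigid-sphere model
#' enters the concentrated regime and is expected to over-predict
#' hindrance.
#'
#' @param polymer a [polymer_spec()].
#' @param solute a [solute_spec()] or solute radius in nm.
#' @param concentrations positive concentrations.
#' @param unit concentration unit (see [center_spacing()]).
#' @param sweep optional precomputed `"model_curve"` from
#'   [homogenization_sweep()]; by default a cached sweep over
#'   `rho = 0, 0.04, ..., 1.4` at `n = 48` is used (memoized, so repeated
#'   calls are fast).
#' @param n sweep base resolution when `sweep` is NULL.
#' @return A data frame with columns `c`, `L_nm`, `rho`, `De_over_D0`,
#'   `concentrated`.
#' @export
#' @examples
#' \donttest{
#' lib <- polymer_library()
#' predict_diffusivity(lib$polymers$dextran500, lib$solutes$rnase,
#'                     c(0.2, 1, 5, 10))
#' }
predict_diffusivity <- function(polymer, solute, concentrations,
                                unit = c("mg/ml", "percent", "g/cm3"),
                                sweep = NULL, n = 48L) {
  stopifnot(inherits(polymer, "polymer_spec"))
  unit <- match.arg(unit)
  .check_positive(concentrations, "concentrations")
  a <- if (inherits(solute, "solute_spec")) solute$hydrodynamic_radius
       else as.numeric(solute)
  L <- center_spacing(polymer, concentrations, unit)
  rho <- rho_parameter(polymer$hydrodynamic_radius, a, L)
  bad <- rho >= sqrt(2)
  if (any(bad))
    stop(sprintf(paste0("concentration %g gives rho = %.3f >= sqrt(2): ",
                        "no connected void"),
                 concentrations[which(bad)[1]], rho[which(bad)[1]]),
         call. = FALSE)
  if (is.null(sweep))
    sweep <- homogenization_sweep(seq(0, 1.4, by = 0.04), n = n)
  if (max(rho) > max(sweep$rho) + 1e-9)
    stop("sweep does not cover the required rho range", call. = FALSE)
  f <- splinefun(sweep$rho, sweep$De_over_D0, method = "monoH.FC")
  ctheta <- geometric_overlap_concentration(polymer)       # % w/v
  c_pct <- .to_g_per_cm3(concentrations, unit) * 100
  data.frame(c = concentrations, L_nm = L, rho = rho,
             De_over_D0 = f(rho), concentrated = c_pct > ctheta)
}
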