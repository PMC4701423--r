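# Geometry module: measurable polymer/solute/concentration parameters ->
# dimensionless obstruction geometry (L, rho, phi).
#
# Unit policy: lengths in nm, molecular weight in g/mol (kDa accepted),
# concentrations normalized internally to g/cm^3 (1 mg/ml = 1e-3 g/cm^3,
# 1 % w/v = 10 mg/ml).

.to_g_per_cm3 <- function(c, unit = c("mg/ml", "percent", "g/cm3")) {
  unit <- match.arg(unit)
  switch(unit,
    "mg/ml"   = c * 1e-3,
    "percent" = c * 1e-2,
    "g/cm3"   = c)
}

.check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be a positive finite number", name), call. = FALSE)
  invisible(x)
}

#' Polymer specification
#'
#' Bundles the measurable properties of a polymer: molecular weight,
#' hydrodynamic radius and (optionally) gyration radius.
#'
#' @param name label for the polymer.
#' @param mw molecular weight (g/mol, or kDa with `mw_unit = "kDa"`).
#' @param rh hydrodynamic radius \eqn{R_h} (nm).
#' @param rg gyration radius \eqn{R_g} (nm), optional; needed only for the
#'   coil overlap concentration \code{\link{overlap_concentration}}.
#' @param mw_unit `"g/mol"` (default) or `"kDa"`.
#' @return An object of class `"polymer_spec"`.
#' @seealso [solute_spec()], [polymer_library()]
#' @export
#' @examples
#' polymer_spec("dextran500", mw = 500, rh = 15.9, mw_unit = "kDa")
polymer_spec <- function(name, mw, rh, rg = NULL, mw_unit = c("g/mol", "kDa")) {
  mw_unit <- match.arg(mw_unit)
  if (mw_unit == "kDa") mw <- mw * 1000
  .check_positive(mw, "mw")
  .check_positive(rh, "rh")
  if (!is.null(rg)) .check_positive(rg, "rg")
  structure(list(name = as.character(name), molecular_weight = mw,
                 hydrodynamic_radius = rh, gyration_radius = rg),
            class = "polymer_spec")
}

#' Solute specification
#'
#' @param name label for the solute.
#' @param mw molecular weight (g/mol, or kDa with `mw_unit = "kDa"`).
#' @param a hydrodynamic radius of the solute (nm).
#' @inheritParams polymer_spec
#' @return An object of class `"solute_spec"`.
#' @export
#' @examples
#' solute_spec("rnase", mw = 13.7, a = 1.8, mw_unit = "kDa")
solute_spec <- function(name, mw, a, mw_unit = c("g/mol", "kDa")) {
  mw_unit <- match.arg(mw_unit)
  if (mw_unit == "kDa") mw <- mw * 1000
  .check_positive(mw, "mw")
  .check_positive(a, "a")
  structure(list(name = as.character(name), molecular_weight = mw,
                 hydrodynamic_radius = a),
            class = "solute_spec")
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat(sprintf("<polymer_spec> %s: MW = %g kDa, Rh = %g nm%s\n", x$name,
              x$molecular_weight / 1000, x$hydrodynamic_radius,
              if (is.null(x$gyration_radius)) ""
              else sprintf(", Rg = %g nm", x$gyration_radius)))
  invisible(x)
}

#' @export
print.solute_spec <- function(x, ...) {
  cat(sprintf("<solute_spec> %s: MW = %g kDa, a = %g nm\n", x$name,
              x$molecular_weight / 1000, x$hydrodynamic_radius))
  invisible(x)
}

#' Built-in polymer and solute library
#'
#' Reads the small data file shipped with the package holding the properties
#' of the polymers (Dextran500, Dextran70, Ficoll400) and the solute (RNase)
#' used throughout the examples, including their reference coil overlap
#' concentrations.
#'
#' @return A list with elements `polymers` (named list of
#'   [polymer_spec()] objects, each carrying a `cstar_percent` attribute
#'   where a literature coil-overlap concentration is available) and
#'   `solutes` (named list of [solute_spec()] objects).
#' @export
#' @examples
#' lib <- polymer_library()
#' lib$polymers$dextran500
polymer_library <- function() {
  path <- system.file("extdata", "polymers.json", package = "crowddiff",
                      mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  polymers <- lapply(raw$polymers, function(p) {
    sp <- polymer_spec(p$name, mw = p$mw_kda, rh = p$rh_nm,
                       rg = p$rg_nm, mw_unit = "kDa")
    attr(sp, "cstar_percent") <- p$cstar_percent
    sp
  })
  names(polymers) <- vapply(polymers, `[[`, "", "name")
  solutes <- lapply(raw$solutes, function(s)
    solute_spec(s$name, mw = s$mw_kda, a = s$rh_nm, mw_unit = "kDa"))
  names(solutes) <- vapply(solutes, `[[`, "", "name")
  list(polymers = polymers, solutes = solutes)
}

.mw_of <- function(x) {
  if (inherits(x, "polymer_spec") || inherits(x, "solute_spec"))
    x$molecular_weight
  else as.numeric(x)
}

#' Center-to-center spacing of polymer molecules
#'
#' For a simple cubic arrangement at mass concentration `c`, each polymer
#' occupies a cube of side \eqn{L = (M_W / (c N_A))^{1/3}}.
#'
#' @param polymer a [polymer_spec()] or a molecular weight in g/mol.
#' @param c polymer concentration (positive).
#' @param unit concentration unit: `"mg/ml"` (default), `"percent"`
#'   (% w/v, = 10 mg/ml) or `"g/cm3"`.
#' @return Spacing \eqn{L} in nm (vectorized over `c`).
#' @export
#' @examples
#' center_spacing(5e5, 0.2)   # dilute dextran500: 160.7 nm
center_spacing <- function(polymer, c, unit = c("mg/ml", "percent", "g/cm3")) {
  mw <- .mw_of(polymer)
  .check_positive(mw, "molecular weight")
  .check_positive(c, "c")
  c_g <- .to_g_per_cm3(c, unit)
  (mw / (c_g * AVOGADRO))^(1 / 3) * 1e7   # cm -> nm
}

#' Dimensionless obstruction parameter
#'
#' \eqn{\rho = 2(R + a)/L}: the diameter of the obstruction excluded to the
#' solute center (polymer radius plus solute radius, doubled) over the
#' lattice spacing.  \eqn{\rho = 1} means adjacent obstructions touch;
#' the void between obstructions stays connected up to
#' \eqn{\rho = \sqrt{2}}.
#'
#' @param R polymer hydrodynamic radius (nm), `>= 0`.
#' @param a solute hydrodynamic radius (nm), `>= 0`.
#' @param L center-to-center spacing (nm), `> 0`.
#' @return \eqn{\rho} (dimensionless).
#' @export
#' @examples
#' rho_parameter(15.9, 1.8, 160.7)
rho_parameter <- function(R, a, L) {
  if (any(!is.finite(R)) || any(R < 0)) stop("'R' must be >= 0", call. = FALSE)
  if (any(!is.finite(a)) || any(a < 0)) stop("'a' must be >= 0", call. = FALSE)
  .check_positive(L, "L")
  2 * (R + a) / L
}

#' Obstructed volume fraction
#'
#' Fraction of space excluded to the solute center by the periodic spheres
#' of radius \eqn{\rho/2}: \eqn{\phi = \pi\rho^3/6} for \eqn{\rho \le 1}.
#' For \eqn{1 < \rho < \sqrt 2} neighbouring spheres overlap and the
#' per-cell volume of their union is computed by inclusion-exclusion with
#' the six pairwise spherical caps (triple overlaps first appear at
#' \eqn{\rho = \sqrt 2}, where the void disconnects).
#'
#' @param rho obstruction parameter, `0 <= rho < sqrt(2)` (vectorized).
#' @return \eqn{\phi \in [0, 1)}.
#' @export
#' @examples
#' obstructed_fraction(1)    # pi/6
#' obstructed_fraction(1.2)  # overlapping spheres: 0.798
obstructed_fraction <- function(rho) {
  if (any(!is.finite(rho)) || any(rho < 0))
    stop("'rho' must be >= 0", call. = FALSE)
  if (any(rho >= sqrt(2)))
    stop("rho >= sqrt(2): the void between obstructions is disconnected",
         call. = FALSE)
  r <- rho / 2
  phi <- pi * rho^3 / 6
  over <- rho > 1
  if (any(over)) {
    h <- r[over] - 0.5                      # cap height of each pairwise lens half
    vcap <- pi * h^2 * (3 * r[over] - h) / 3
    phi[over] <- (4 / 3) * pi * r[over]^3 - 6 * vcap
  }
  phi
}

#' Coil overlap concentration
#'
#' Concentration at which polymer coils, modelled as spheres of gyration
#' radius \eqn{R_g}, fill space:
#' \eqn{c^* = M_W / (\frac{4}{3}\pi R_g^3 N_A)}.
#'
#' @param polymer a [polymer_spec()] with a gyration radius.
#' @return \eqn{c^*} in % w/v.
#' @seealso [geometric_overlap_concentration()]
#' @export
overlap_concentration <- function(polymer) {
  stopifnot(inherits(polymer, "polymer_spec"))
  if (is.null(polymer$gyration_radius))
    stop("gyration radius R_g is required for the coil overlap concentration",
         call. = FALSE)
  rg_cm <- polymer$gyration_radius * 1e-7
  c_g <- polymer$molecular_weight / ((4 / 3) * pi * rg_cm^3 * AVOGADRO)
  c_g * 100  # g/cm^3 -> % w/v
}

#' Geometric overlap concentration
#'
#' Concentration at which the equivalent hard spheres of hydrodynamic
#' radius \eqn{R_h} on the cubic lattice touch (\eqn{L = 2 R_h}):
#' \eqn{c^\theta = M_W / (8 R_h^3 N_A)}.  Above \eqn{c^\theta} the rigid-
#' sphere model enters the concentrated regime where it is expected to
#' over-predict hindrance.
#'
#' @param polymer a [polymer_spec()].
#' @return \eqn{c^\theta} in % w/v.
#' @export
#' @examples
#' geometric_overlap_concentration(polymer_spec("dex70", 70, 5.8, mw_unit = "kDa"))
geometric_overlap_concentration <- function(polymer) {
  stopifnot(inherits(polymer, "polymer_spec"))
  rh_cm <- polymer$hydrodynamic_radius * 1e-7
  c_g <- polymer$molecular_weight / (8 * rh_cm^3 * AVOGADRO)
  c_g * 100
}

#' System geometry for a polymer-solute pair at a given concentration
#'
#' Combines [center_spacing()], [rho_parameter()] and
#' [obstructed_fraction()] into one description of the dimensionless model
#' geometry.
#'
#' @inheritParams center_spacing
#' @param solute a [solute_spec()] or a solute hydrodynamic radius in nm.
#' @param D0 free diffusivity of the solute in plain solvent (any area/time
#'   unit); stored for downstream rescaling, defaults to 1 (dimensionless).
#' @return An object of class `"system_geometry"` with fields `L` (nm),
#'   `rho`, `phi`, `concentration` (g/cm^3), `D0`, `polymer`, `solute`.
#' @export
#' @examples
#' lib <- polymer_library()
#' system_geometry(lib$polymers$dextran500, lib$solutes$rnase, 5)
system_geometry <- function(polymer, solute, c,
                            unit = c("mg/ml", "percent", "g/cm3"), D0 = 1) {
  stopifnot(inherits(polymer, "polymer_spec"))
  a <- if (inherits(solute, "solute_spec")) solute$hydrodynamic_radius
       else as.numeric(solute)
  L <- center_spacing(polymer, c, unit)
  rho <- rho_parameter(polymer$hydrodynamic_radius, a, L)
  if (any(rho >= sqrt(2)))
    stop(sprintf(paste0("rho = %.3f >= sqrt(2): obstructions leave no ",
                        "connected void at this concentration"), max(rho)),
         call. = FALSE)
  structure(list(L = L, rho = rho, phi = obstructed_fraction(rho),
                 concentration = .to_g_per_cm3(c, unit), D0 = D0,
                 polymer = polymer, solute = solute),
            class = "system_geometry")
}

#' @export
print.system_geometry <- function(x, ...) {
  cat("<system_geometry>\n")
  df <- data.frame(c_g_cm3 = x$concentration, L_nm = x$L,
                   rho = x$rho, phi = x$phi)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}
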