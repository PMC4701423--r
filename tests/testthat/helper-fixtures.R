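# Shared fixtures built in code.

# Table of reference center-to-center spacings for dextran500 + RNase
# (concentration in mg/ml, spacing in nm, printed to the shown precision).
ref_spacing <- data.frame(
  c = c(0.2, 0.4, 0.6, 0.8, 1, 3, 5, 7, 10, 18, 25, 50),
  L = c(160.7, 127.54, 111.41, 101.23, 93.97, 65.15, 54.95, 49.12, 43.62,
        35.82, 32.14, 25.5)
)

dextran500 <- polymer_spec("dextran500", 500, 15.9, mw_unit = "kDa")
dextran70 <- polymer_spec("dextran70", 70, 5.8, mw_unit = "kDa")
rnase <- solute_spec("rnase", 13.7, 1.8, mw_unit = "kDa")

# hand-built ensemble_record with prescribed squared displacements, for
# exercising the MSD estimators without a simulation
fake_ensemble <- function(times, sq_disp) {
  structure(list(config = list(model = "synthetic"), times = times,
                 sq_disp = sq_disp),
            class = "ensemble_record")
}

# Monte Carlo point-sampling oracle for the obstructed volume fraction:
# fraction of uniform points in the unit cell within rho/2 of the nearest
# lattice point
phi_oracle <- function(rho, n_points, seed) {
  set.seed(seed)
  p <- matrix(runif(3 * n_points, -0.5, 0.5), ncol = 3)
  d <- pmin(abs(p), 1 - abs(p))
  mean(rowSums(d^2) < (rho / 2)^2)
}
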