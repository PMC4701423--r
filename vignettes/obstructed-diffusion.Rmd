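---
title: "Predicting obstructed solute diffusivity in macromolecular solutions"
author: "crowddiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting obstructed solute diffusivity in macromolecular solutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crowddiff)
```

## The model

A small solute (say a globular protein at trace concentration) diffuses in
water among dissolved polymer molecules. crowddiff models the polymers as
*stationary, impenetrable spheres* of hydrodynamic radius $R$ placed on a
simple cubic lattice with center-to-center spacing $L$, and the solute as a
sphere of hydrodynamic radius $a$ undergoing Brownian motion with free
diffusivity $D_0$ and specular reflection at the obstacles. Because the
solute center cannot approach an obstacle center closer than $R + a$, the
obstruction seen by the solute center is a sphere of radius $R + a$, and
the entire geometry reduces to one dimensionless number,

$$\rho = \frac{2(R + a)}{L}, \qquad
  L = \left(\frac{M_W}{c\,N_A}\right)^{1/3},$$

where $M_W$ is the polymer molecular weight, $c$ its mass concentration and
$N_A$ Avogadro's number (fixed at $6.022\times 10^{23}\,\mathrm{mol}^{-1}$,
the precision used in the reference tables, so that tabulated spacings
reproduce digit-for-digit). At $\rho = 1$ neighbouring obstructions touch;
at $\rho = \sqrt 2$ the void between them disconnects and long-range
transport ceases. The obstructed volume fraction is
$\phi = \pi\rho^3/6$ for $\rho \le 1$; for $1 < \rho < \sqrt 2$ the package
uses the inclusion–exclusion volume of the overlapping periodic spheres
(six pairwise spherical caps; triple overlaps first appear at
$\rho = \sqrt2$), verified against a Monte Carlo point-sampling oracle.

Assumptions worth keeping in mind: obstacles are rigid, stationary,
spherical and periodic; there is no solute–polymer attraction or
repulsion beyond hard exclusion, and no hydrodynamic interaction. The
stationarity assumption is sensible when the polymer is several-fold
larger than the solute.

## Homogenization: from the unit cell to $D_e$

When the observation scale is much larger than $L$, periodic
homogenization replaces the obstructed medium by an equivalent homogeneous
one with effective diffusivity $D_e$. The input is the corrector problem
on one periodic cell (the unit cube minus the central sphere of radius
$\rho/2$): find $\omega_j$ harmonic in the fluid, periodic across the cube
faces, with reflecting obstacle walls carrying the Neumann data
$\nabla\omega_j\cdot n = -e_j\cdot n$. Then

$$\frac{D_e}{D_0} = \frac{1}{|\bar\Omega|}\int_{\bar\Omega}
  \Bigl(1 + \frac{\partial\omega_j}{\partial x_j}\Bigr)\,dx ,$$

with $|\bar\Omega|$ the fluid volume. By cubic symmetry the result is
independent of $j$, and the full tensor (`effective_diffusivity_tensor()`)
is isotropic. Note the normalization: $D_e$ as defined here is the
diffusivity experienced by solute that *starts in the fluid phase*;
$D_e(1-\phi)$ (reported as `De_scaled`) is the appropriate coefficient
when solute is initially spread over obstructed regions too. For
comparison with FCS measurements on freshly prepared solutions the
unscaled $D_e$ is the relevant quantity, because the solute never had time
to partition into the polymer coils.

### Numerics

The solver is a flux-conservative finite-volume scheme on a regular
$n^3$ grid. A cell is solid when its center lies inside the obstruction
(distance-to-nearest-lattice-point test, which handles overlapping
periodic spheres for $\rho > 1$ automatically); face transmissibilities
across solid faces are zero, which realises the reflecting boundary as a
staircase. The corrector is obtained as $\chi_j = \omega_j + x_j$ with a
periodic jump, giving a symmetric singular linear system solved by
Jacobi-preconditioned conjugate gradients to a relative residual of
$10^{-8}$, with the gauge fixed by a zero-mean projection over fluid
cells. $D_e/D_0$ is evaluated by the face-flux quadrature consistent with
the stencil. Two independent correctness oracles back this up in the test
suite: a layered medium, where the scheme reproduces the exact
series-resistance (harmonic-mean) and parallel (arithmetic-mean)
conductivities to machine precision, and the dilute limit
$D_e/D_0 \to 1 - \phi/2 + O(\phi^2)$.

The staircase boundary carries a first-order error with a sizable
constant (at $\rho = 0.92$, $n = 64$ is still $\approx 0.019$ low), so
`homogenization_sweep()` solves each point at $n$ and $2n$ and reports the
Richardson extrapolation $2D_e(2n) - D_e(n)$; the grid-doubling difference
doubles as a per-point refinement diagnostic (`refine_flag`). With the
default $n = 64$ base grid this reproduces the exponential-law exponent
below to three decimals. Above $\rho = 1.2$ the auto-resolution rule
switches to a single $n = 128$ solve: near the percolation limit the void
narrows to thread-like channels along the cube edges that even fine
staircase grids under-resolve (at $\rho = 1.40$ the discrete channel
conductance collapses), so values there are qualitative.

### The exponential law and effective-medium comparators

Over $0 \le \rho \le 0.92$ the computed curve is captured to a few parts
in a thousand by the one-parameter law $D_e/D_0 = e^{-k\rho^3}$;
`fit_k()` estimates $k$ by least squares (a minimax option exists — the
two differ by less than the fit's own error bound) and reports the
maximum absolute deviation. The classical Maxwell effective-medium
formula with impenetrable inclusions,
$D_e/D_0 = (1 - \Lambda\rho^3/12)/(1 + \Lambda\rho^3/24)$ with
$\Lambda = 2\pi$, describes the *volume-average* convention; dividing it
by $1-\phi$ (`scaled_maxwell()`) converts it to the fluid-phase
convention and brings it close to the homogenization curve over most of
the sweep (within 0.03 up to $\rho \approx 0.92$). The naive accessible
volume fraction $1-\phi$ sits well below both — obstructed diffusion is
not a volume average.

## Monte Carlo cross-validation

Two independent stochastic simulators cross-check the continuum result;
neither involves a spatial grid, so they are immune to the staircase
error discussed above.

**Reflected Wiener walks** (`simulate_wiener()`): Euler–Maruyama steps
with per-axis variance $2D_0\,dt$; a step whose endpoint lands inside an
obstruction is resolved by specularly reflecting the residual sub-segment
at the ray–sphere entry point, iterated as needed. Exactly tangent
contact counts as no collision (the zero-chord limit of oblique
incidence). The default $dt$ keeps the RMS step below a tenth of the
narrowest void passage ($L(1-\rho)$ along the axis for $\rho<1$, the
face-diagonal channel width $L(\sqrt2-\rho)$ above); halving $dt$ moves
the fitted diffusivity by less than its confidence half-width, which is
the operative accuracy criterion for the scheme. In the wedge where
obstructions (nearly) touch, a step can undergo arbitrarily many
ever-smaller bounces; once the chord advance stalls below
$10^{-10}(R+a)$ the walker is parked on the surface for the remainder of
that step, a truncation far below any observable.

**Kinetic (velocity-jump) walks** (`simulate_kinetic()`): rectilinear
flights with i.i.d. exponential lengths (mean $\lambda$), i.i.d.
exponential durations (mean $\tau$) and isotropic directions, reflecting
specularly and continuing the remaining flight length at each collision;
the flight duration is consumed uniformly along its (possibly reflected)
path when recording positions. For the unobstructed walk
$E[\ell^2] = 2\lambda^2$ gives $\mathrm{MSD}(t) \to (2\lambda^2/\tau)\,t$,
so the default $\tau = \lambda^2/(3D_0)$ makes the model reproduce
$D_0$ exactly — the factor 2 matters; pairing the same $\tau$ with the
sometimes-quoted asymptote $\lambda^2 t/\tau$ would give half the
intended diffusivity, and the test suite pins the correct calibration.
The default $\lambda = 0.2$ (with $L = 5$, lengths in nm) represents the
mean free path of a water molecule in water — a deliberately *pessimistic*
choice, since a larger solute has a shorter mean free path, making the
Wiener approximation hardest to satisfy. Halving $\lambda$ leaves the
fitted diffusivity unchanged at CI level.

Ensembles record 250 positions at equidistant times (the first at
$t = 0$) for $N$ walkers started either at the cell body-center
(equidistant from the eight nearest obstructions) or uniformly over the
void. Every walker runs on its own counter-seeded xoshiro256++ stream, so
ensembles are bit-reproducible from the seed and independent of
execution order. The default horizon $t_\mathrm{max} = (4L)^2/(6D_0)$
lets the RMS displacement cross about four cells — hindered-but-normal
behaviour is established within roughly two cell spacings, so the window
comfortably brackets the transition.

## MSD analysis

`estimate_msd()` averages the per-walk squared displacements;
`fit_de()` fits the least-squares line *through the origin* to MSD vs
$t$ and reports $D_e = \mathrm{slope}/6$. The default fit window is the
full recorded range; an option restricts to the linear tail
($t \ge t_\mathrm{max}/2$) because walks started mid-cell diffuse freely
until their first collision, which biases the full-window slope slightly
upward (with the default horizon the bias is a few parts in $10^4$,
well below the statistical noise at $N = 10^4$). The 95% confidence
interval applies the same through-origin fit to every individual walk and
uses $\bar s \pm 1.96\,\mathrm{sd}(s_i)/\sqrt N$ — the per-walk slopes are
i.i.d. and their mean is exactly the ensemble slope; a walker-resampling
bootstrap is available behind a flag and agrees.

`loglog_diagnostic()` separates anomalous from normal diffusion: on
segments where $\mathrm{MSD} = C t^\alpha$, $\ln(\mathrm{MSD}/t)$ vs
$\ln t$ (natural logarithms throughout) is linear with slope $\alpha - 1$.
A continuous piecewise-linear fit (truncated-power basis; knots chosen by
exhaustive search over a quantile grid, SSE-minimal) estimates the
$\alpha_i$. For the reflected walks both the small-$t$ and large-$t$
plateaus are flat ($\alpha = 1$) at heights $\ln 6D_0$ and $\ln 6D_e$;
the transition between them is curved rather than power-law, and its
shape depends on the initial-condition mode — a diagnostic, not a fitted
regime.

## FCS

Fluorescence correlation spectroscopy measures the autocorrelation
$G(\tau)$ of intensity fluctuations in a confocal volume; for a single
monodisperse component in normal diffusion

$$G(\tau) = 1 + \frac1N\,\frac{1}{1+\tau/\tau_d}\,
  \frac{1}{\sqrt{1 + p\,\tau/\tau_d}},\qquad
  \tau_d = \frac{r_0^2}{4D},$$

with $N$ the mean occupancy, $r_0$ the radial beam waist and
$p = (r_0/z_0)^2$ the instrumental structure constant. `fit_fcs()`
estimates $(N, \tau_d)$ by Levenberg–Marquardt least squares with $p$
held fixed, as is standard for a calibrated instrument; starting values
come from the zero-delay amplitude and the half-decay delay. Triplet and
multi-component terms are deliberately omitted (single-component fits
suffice for inert polymer–solute pairs in this regime). The default
$p = 0.04$ is a typical confocal aspect ratio, not an instrument
calibration — supply your own whenever known. The measured normalized
diffusivity is the ratio of diffusion times, $D_e/D_0 = \tau_0/\tau_d$.

`synthesize_fcs()` generates model curves with additive zero-mean
Gaussian amplitude noise. This emulates the shape and noise scale of real
correlator output but none of its pathologies — no afterpulsing,
triplet shoulder, baseline drift or correlated noise — so the
parameter-recovery tests demonstrate fitter correctness, not robustness
to instrument artefacts. The end-to-end test drives a full concentration
series (geometry → homogenization → synthetic curves → refit) and
recovers the model curve within fit noise.

## Problem sizes and defaults used in the shipped checks

The packaged tests and the acceptance script run the homogenization sweep
at $\rho = 0, 0.04, \dots, 0.92$ on base grids of $n = 48$ (tests) or
$n = 64$ (script), each Richardson-paired with $2n$, and Monte Carlo
ensembles of $N = 10^4$ walkers; confidence-interval widths at the
reference ensemble size $N = 10^5$ are obtained by the exact
$1/\sqrt N$ scaling of the per-walk-slope standard error. These sizes
were chosen so each check completes in minutes on a single core while
leaving every tolerance dominated by the method, not the budget.

## Known limitations

* The rigid-sphere geometry over-predicts hindrance in the concentrated
  regime ($c > c^\theta = M_W/(8R_h^3N_A)$), where real coils interpenetrate
  and entangle; `predict_diffusivity()` flags such concentrations rather
  than refusing them.
* Near the percolation limit ($\rho \gtrsim 1.3$) the staircase grid
  under-resolves the thread-like channels; sweep values there are
  order-of-magnitude only. The Monte Carlo simulators remain usable.
* The scaled Maxwell formula is an $O(\phi)$ effective-medium result: it
  tracks the homogenization curve within 0.03 up to $\rho \approx 0.92$
  but overshoots by about 0.07 at sphere contact ($\rho = 1$), where both
  Monte Carlo simulators independently confirm the homogenization value
  ($D_e/D_0 \approx 0.72$ vs 0.79 for the scaled formula).
* The kinetic model with the pessimistic $\lambda = 0.2$ carries a small
  finite-mean-free-path correction relative to the Wiener limit
  (well below the $N = 10^4$ confidence width at $\rho \le 1$); it is a
  validation of the Wiener approximation, not a replacement for it.
* Mobile obstacles, polydispersity, non-cubic or random placements, and
  solute–polymer interactions are out of scope by design; the periodic
  framework is the simplest member of the homogenization family and the
  natural base for such extensions.
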