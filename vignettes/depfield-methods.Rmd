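---
title: "Modelling the DEP force field of interdigitated-electrode devices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the DEP force field of interdigitated-electrode devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depfield)
```

## The physical problem

A common architecture for dielectrophoretic (DEP) cell capture is a
parallel-plate microfluidic channel whose floor carries interdigitated
powered/grounded finger electrodes and whose lid is a planar grounded
counter-electrode.  An AC drive creates a strongly non-uniform field near
the electrode edges; a polarisable cell of diameter $d_c$ suspended in a
medium of permittivity $\epsilon_l$ experiences the time-averaged force

$$\mathbf{F}_\mathrm{DEP}
  = 2\pi\,\epsilon_l\left(\tfrac{d_c}{2}\right)^{3}
    \mathrm{Re}(\beta)\,\nabla |\mathbf{E}|^{2},$$

with $\beta$ the Clausius–Mossotti (CM) factor.  Designing such a device
requires (i) $\mathrm{Re}(\beta)$ as a function of drive frequency and
medium conductivity, and (ii) the spatial field $\nabla|\mathbf{E}|^2$ as a
function of electrode width, spacing and channel height.  This package
provides both, with an analytic series solution for the field — important
because $\nabla|\mathbf{E}|^2$ involves second derivatives of the
potential, which discrete (FEM/FD) solutions reproduce poorly near the
electrode-edge singularities (they oscillate spatially there), while a
series solution is smooth by construction.

## Cell polarisability: the single-shell model

A live cell is modelled as a conducting interior (effective permittivity
$\epsilon_c'$, conductivity $\sigma_c'$) wrapped in a thin insulating
membrane of capacitance per area $c_m$.  In the thin-shell limit the cell's
effective complex permittivity is the series combination

$$\epsilon_\mathrm{cell}^{*}
  = \frac{c_m R\,\epsilon_i^{*}}{c_m R + \epsilon_i^{*}},
  \qquad \epsilon_i^{*} = \epsilon_c' + \frac{\sigma_c'}{j\omega},
  \qquad R = d_c/2,$$

and $\beta = (\epsilon_\mathrm{cell}^* - \epsilon_l^*)/
(\epsilon_\mathrm{cell}^* + 2\epsilon_l^*)$.  `cm_single_shell()` evaluates
the equivalent closed time-constant form (documented on its help page) in
terms of $\tau_c^* = c_m d_c/2\sigma_c'$, $\tau_c = \epsilon_c'/\sigma_c'$,
$\tau_l^* = c_m d_c/2\sigma_l$, $\tau_l = \epsilon_l/\sigma_l$; the
shelled-sphere route (`cell_permittivity()` + `cm_factor()`) is retained as
an independent cross-check and the test suite verifies the two agree to
machine precision.  Physical anchors of this form: $\beta \to -1/2$ as
$\omega \to 0$ (the insulating membrane screens the interior, so the cell
behaves as a non-conducting sphere) and
$\beta \to (\epsilon_\infty-\epsilon_l)/(\epsilon_\infty+2\epsilon_l)$ with
$\epsilon_\infty = c_mR\,\epsilon_c'/(c_mR+\epsilon_c')$ at high frequency;
$\mathrm{Re}(\beta) \in [-1/2, 1]$ throughout, which the tests check over
randomised physical parameter sets.

Quantitative CM spectra require measured cell properties.  The package
ships a *synthetic* MCF10A-like parameter set in its tests and examples
($d_c = 15\,\mu$m, $c_m = 0.01$ F/m², $\epsilon_c' = 50\,\epsilon_0$,
$\sigma_c' = 0.5$ S/m); in the standard low-conductivity medium
($\epsilon_l = 6.9\times10^{-10}$ F/m, $\sigma_l = 10^{-3}$ S/m) it gives a
broad positive-DEP plateau with $\mathrm{Re}(\beta) \approx 0.93$–$0.97$
across 0.1–10 MHz, consistent with operating such devices near 8.5 MHz at
$\mathrm{Re}(\beta)\approx 0.98$.

## Field model

The fingers are long and aligned with the flow, so the field is modelled
in the 2D cross-section.  One half-period spans the powered-finger centre
line ($x^*=0$) to the grounded-finger centre line ($x^*=1$); the electrode
plane is $y^*=1$ and the grounded lid $y^*=0$ ($x = Lx^*$, $y = Hy^*$; $L$
the finger pitch, $2w$ the finger width, $d = L-2w$ the spacing, $H$ the
channel height).  The RMS-electrostatic potential obeys

$$\frac{\partial^2\varphi}{\partial x^{*2}}
 + \left(\frac{L}{H}\right)^2\frac{\partial^2\varphi}{\partial y^{*2}} = 0$$

with $\varphi = V_\mathrm{rms}$ on the powered finger, $0$ on the grounded
finger and the lid, symmetry (Neumann) side walls, and the *insulating gap
condition* $\partial\varphi/\partial y^* = 0$ on the inter-electrode gap.
The Dirichlet/Neumann mix on one boundary prevents separation of
variables.

### The cubic gap approximation and its calibration

The gap condition is replaced by Dirichlet data from a one-parameter cubic
family.  With $s = (x^*-\tfrac12)/(\tfrac12-w/L)$ ($s=\mp1$ at the
powered/grounded edges),

$$\varphi(x^*,1) = \frac{V_\mathrm{rms}}{\pi}\left[
  \frac{\pi}{2} - C s - \left(\frac{\pi}{2}-C\right)s^{3}\right].$$

Two properties make this family the right shape.  First, it is
*continuous* with the electrode potentials at both edges for every $C$, so
the Fourier coefficients decay like $n^{-2}$ and the term-wise
differentiated (field) series converges on the electrode plane.  Second,
it is the two-term odd-polynomial approximation of the *exact* gap
potential of an isolated coplanar electrode pair, which conformal mapping
gives as $\varphi = (V_\mathrm{rms}/\pi)(\pi/2 - \arcsin s)$
(`gap_reference_halfspace()`).  Because the family is linear in $C$, the
least-squares calibration against that reference is closed-form
(`fit_gap_constant()`); with 512 interior samples it yields

```{r fitc}
p <- device_preset("A")
fit <- fit_gap_constant(gap_fit_reference(p$geometry, p$drive),
                        p$geometry, p$drive)
coef(fit)
```

i.e. $C = 0.754718$, used as the package default.  The reference depends
on the gap coordinate only through $s$, so this constant is
geometry-universal within the model.  Fitting instead against the gap
trace of the finite-channel mixed solution (`gap_fit_reference_fd()`)
yields a geometry-dependent optimum (about $0.69$ at $H/L=5$, $w/L=0.25$)
because the grounded lid superimposes an even "sag" on the trace and draws
the odd component steeper; the half-space reference is the documented
calibration and reproduces the behaviour of the truncated-arcsin family.

### Series solution

With the replaced boundary the solution separates:

$$\varphi = a_0 y^* + 2\sum_{n\ge1} I_n \cos(k_n x^*)\,
  \frac{\sinh(k_n \frac{H}{L} y^*)}{\sinh(k_n \frac{H}{L})},
  \qquad k_n = n\pi,\; a_0 = \frac{V_\mathrm{rms}}{2},$$

where $I_n = \int_0^1 f(x^*)\cos(k_n x^*)\,dx^*$ are the cosine
projections of the boundary profile.  Two coefficient routes are
implemented and reconciled to $10^{-9}$ relative in the tests: exact
piecewise integration (`fourier_coefficients_closed_form()`, the default)
and adaptive quadrature (`fourier_coefficients_quadrature()`, the
normative oracle).  Even-order coefficients vanish by the antisymmetry
$f(x^*) + f(1-x^*) = V_\mathrm{rms}$, which propagates to the mirror
identity $\varphi(x^*,y^*) + \varphi(1-x^*,y^*) = V_\mathrm{rms}\,y^*$.

Numerical choices:

* **Stored coefficients.** The package stores the reduced $I_n$, not
  $I_n/\sinh(k_n H/L)$: at $H/L = 5$ the $\sinh$ overflows for $n \ge 45$.
  Evaluation folds the ratio
  $\sinh(k_n\frac{H}{L}y^*)/\sinh(k_n\frac{H}{L})$ into the exp-difference
  form $e^{a(y^*-1)}(1-e^{-2ay^*})/(1-e^{-2a})$, which is stable for all
  $n$ and $y^*$.
* **Series length.** The default $n = 10{,}000$ keeps the mean boundary
  reconstruction error below $0.5\,\%$ of $V_\mathrm{rms}$ away from the
  electrode edges ($\pm0.005$ excluded) and is used for all verification
  work; the parametric sweep uses $n = 2{,}000$ per point, which a
  doubling check shows is ample for surface-averaged quantities.
* **Derivatives.** $\mathbf{E} = -\nabla\varphi$,
  $\nabla|\mathbf{E}|^2$ and $\mathbf{F}_\mathrm{DEP}$ are evaluated by
  term-wise analytic differentiation with the $1/L$, $1/H$ metric factors;
  curl- and divergence-freedom reduce the four field derivatives to two
  independent sums.  Finite differences of the potential cross-check both
  in the tests.
* **Normalisation.** $\varphi^* = \varphi/V_\mathrm{rms}$,
  $\mathbf{E}^* = \mathbf{E}H/V_\mathrm{rms}$ and
  $F^*_\mathrm{DEP} = |\mathbf{F}_\mathrm{DEP}|/F_R$ with
  $F_R = 2\pi\epsilon_l(d_c/2)^3\mathrm{Re}(\beta)V_\mathrm{rms}^2/H^3$;
  all normalised quantities are independent of the drive amplitude.
* **Drive.** The preset drive is 10 V peak-to-peak, i.e.
  $V_\mathrm{rms} = 5/\sqrt2 \approx 3.536$ V; both `Vpp` and `Vrms` are
  accepted.
* **Gibbs treatment.** None: the truncated series is used as-is, matching
  the plain-sum evaluation the verification numbers refer to.

### Finite-difference oracle

The *true* mixed problem is solved by second-order finite differences as
an independent check (`solve_mixed_bvp()`); the same discretisation with
Dirichlet gap data (`solve_dirichlet_bvp()`) isolates discretisation error
from the Dirichlet-replacement error.  Design points:

* 5-point stencil on an edge-aligned uniform grid ($(n_x-1)\,w/L$
  integral), Neumann closures by second-order ghost reflection;
  Dirichlet-meets-Neumann nodes take the Dirichlet value.
* The grid chooser pairs $n_y-1 = \frac{H}{L}(n_x-1)$ so the scaled
  problem is isotropic; point smoothers then work well.
* Solvers: sparse Cholesky of the symmetrically scaled system below
  $6\times10^5$ nodes; above that, geometric multigrid — V(2,2) cycles,
  red–black Gauss–Seidel, full-weighting restriction, bilinear
  prolongation, Cholesky on the coarsest level — iterated to a relative
  residual of $10^{-10}$ (observed contraction $\approx 0.07$ per cycle),
  far below the discretisation error so the oracle never limits accuracy.
* Verification grids: $721\times3601$ ($\approx2.6\times10^6$ nodes) as
  the reference, $1441\times7201$ ($\approx10^7$) for the convergence
  check.  The average relative $|\mathbf{E}|$ change between the two,
  excluding one coarse cell around each electrode edge, is
  $\approx 0.013\,\%$.  Interior pointwise convergence is first order, not
  second: the $r^{1/2}$ potential singularity at each Dirichlet/Neumann
  junction pollutes the uniform-grid solution globally.

### Accuracy metrics

The headline accuracy statement compares series and oracle along the
electrode plane as average relative errors $\Delta\varphi^*$ and
$\Delta E^*$.  `error_report()` computes three variants (the averaging
rule is a genuine modelling choice):

* `segmented` (default): integral relative error
  $\sum|q_s-q_{fd}|/\sum|q_{fd}|$ over the segment where each quantity is
  *not imposed by the boundary conditions* — $\varphi^*$ over the gap (on
  the electrodes it equals the Dirichlet data in both solutions), $E^*$
  over the electrodes (on the gap the true normal field vanishes by the
  very Neumann condition the Dirichlet replacement gives up, so a gap
  comparison measures the discarded constraint, not field accuracy).
  Electrode-edge neighbourhoods of $\pm0.01$ in $x^*$ are excluded — the
  continuum field diverges there.
* `pointwise`: mean of $|q_s-q_{fd}|/\max(|q_{fd}|, 10^{-3})$ over the
  whole line (floored where the reference vanishes).
* `scaled`: mean absolute deviation in percent of the normalisation scale.

At Type A ratios with $n=10{,}000$ and $C=0.75480$ the default variant
gives $\Delta\varphi^* = 6.20\,\%$ and $\Delta E^* = 7.02\,\%$ (the
`pointwise` variant gives $4.2\,\%$ and $13.9\,\%$; the spread between
variants is a useful reminder that such single-number accuracy summaries
depend strongly on the rule).  The dominant error is the Dirichlet
replacement itself, not series truncation: the finite channel's true gap
trace is not antisymmetric (its midpoint sits at $0.473\,V_\mathrm{rms}$,
pulled below $V_\mathrm{rms}/2$ by the grounded lid), and no member of the
antisymmetric cubic family can follow that.

### Parametric study

`mean_surface_force()` averages $|\mathbf{F}_\mathrm{DEP}|$ over the
powered-electrode segment at a small fixed dimensionless depth below the
electrode plane (default $10^{-3}$, i.e. 0.5 µm at $H = 500$ µm, with 256
samples).  The offset is part of the definition: the continuum surface
average diverges as the offset goes to zero (the edge force grows like the
inverse square of the distance to the edge), and halving the offset moves
the average by roughly 30 %.  Absolute values therefore depend on the
recipe; *trends across geometries at a fixed recipe* do not, and those are
what `sweep_electrode_geometry()` reports over a grid of electrode widths
and spacings at fixed channel height ($L = 2w+d$ per point).  On a
$40\times40$ sweep of $2w, d \in [5, 60]$ µm at $H = 500$ µm the force
decreases monotonically with spacing at every width, and the mean absolute
central-difference sensitivity to spacing exceeds that to width — the
design finding that electrode spacing, not width, controls capture
strength.  A similarity check ($F \propto V_\mathrm{rms}^2/s^3$ under
joint rescaling of $w, d, H$ by $s$) guards the implementation.

## What the verification does and does not show

All checks are desk-scale and deterministic: they verify the internal
consistency of the analytic solution, its agreement with an independent
discretisation of the true mixed problem, and the qualitative force-field
structure (edge concentration, midline minimum, two-to-three-order decay
over ~30 µm of height).  They do not model fluid flow or drag, Joule
heating, electrode passivation layers, 3D end effects of finite fingers,
AC phase-resolved dynamics, or cell–cell interactions — so quantitative
capture predictions for a real device still require flow experiments; the
model ranks geometries and picks operating frequencies.

## Known limitations

* The cubic gap profile is calibrated against the isolated-gap conformal
  solution; for very shallow channels ($H/L \lesssim 0.2$) the lid
  interacts strongly with the gap and the approximation degrades.
* $\mathrm{Re}(\beta)$ accuracy is bounded by knowledge of the cell's
  membrane capacitance and effective interior properties; the shipped
  values are synthetic placeholders.
* The FD oracle uses uniform grids; near-edge quantities converge slowly
  (first order) and the edge cells are excluded from all metrics.
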