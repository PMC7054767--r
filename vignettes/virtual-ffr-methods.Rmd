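---
title: "Virtual FFR from 2D coronary haemodynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual FFR from 2D coronary haemodynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vffr)
```

Fractional flow reserve (FFR) is the clinical index used to decide whether
a coronary stenosis is haemodynamically significant: the ratio of the mean
pressure distal to the lesion to the mean aortic pressure, measured with a
pressure-wire sensor under maximal vasodilation. `vffr` simulates this
measurement *in silico*: pulsatile blood flow through a 2D branching
coronary geometry is solved with a shear-thinning finite-element model and
lumped-parameter outflow conditions, and the FFR is computed exactly the
way the clinical device computes it — cycle-wise temporal means of an
aortic sampling box and of the pressure on the sensor-disk contour.

This vignette records the models, the parameters and their defaults, the
numerical choices, and what the synthetic test fixtures can and cannot
say about real coronary data.

## Flow model

Blood is an incompressible generalized-Newtonian fluid with density
$\rho_f$ and the Carreau viscosity
$$\mu(s) = \mu_\infty + (\mu_0 - \mu_\infty)\left(1 + (\lambda s)^2\right)^{(n-1)/2},$$
where the shear rate is $s(u) = \sqrt{2\,D(u)\!:\!D(u)}$ with
$D(u) = (\nabla u + \nabla u^T)/2$. The momentum/continuity system
$$\rho_f \partial_t u + \rho_f (u\!\cdot\!\nabla)u
  - \nabla\!\cdot\!\big(2\mu(s(u))D(u)\big) + \nabla p = f,
  \qquad \nabla\!\cdot\!u = 0$$
is posed on the 2D lumen with no-slip walls (vessel walls are treated as
rigid and impermeable; the sensor disk is a true obstacle with a no-slip
contour). A constant-viscosity Newtonian variant is provided for model
comparisons; because nothing pins down which constant a Newtonian
comparison should use, both the high-shear plateau (0.0032 Pa s, the
default) and the low-shear plateau (0.0456 Pa s) are selectable.

Default constants (`carreau_params()`, `fluid_params()`):

| parameter | default | units | meaning |
|---|---|---|---|
| $\mu_0$ | 0.0456 | Pa s | zero-shear viscosity |
| $\mu_\infty$ | 0.0032 | Pa s | infinite-shear viscosity |
| $\lambda$ | 10.03 | s | relaxation time |
| $n$ | 0.344 | — | shear-thinning index |
| $\rho_f$ | 1060 | kg/m$^3$ | blood density |

## Cardiac forcing

The inlet carries the left-coronary waveform
$$I(t) = I_p + I_0 \sin(\pi t / T_{sys}) \ \ (0 \le t \le T_{sys}), \qquad
  I(t) = I_p + I_c \sin\!\big(\pi (t - T_{sys})/(T_c - T_{sys})\big)$$
in diastole, clipped below at zero and $T_c$-periodic, with
$I_p = I_0 = I_c = 10$ cm/s, $T_{sys} = 0.33$ s and $T_c = 0.8$ s
(75 bpm). With these amplitudes the clip never activates and the waveform
is continuous at the phase change. The phase anchors are $t_s = 0$ and
$t_d = T_{sys}$ within each cycle.

Two inlet application modes exist. The default imposes a Dirichlet
parabolic profile whose instantaneous *spatial mean* equals $I(t)$ — this
keeps the inflow speeds at their stated 10–20 cm/s physiological scale
and makes the steady Poiseuille benchmark exact. The alternative
`traction` mode applies $I(t)$ (read in mmHg) as a normal traction, the
literal reading of the boundary line in the governing system; under
traction driving the flux is free to respond to the fluid's resistance,
which is the configuration in which constitutive-law comparisons change
flow magnitudes rather than only profile shapes (see the model-comparison
tests).

## Windkessel outflow

Each outlet couples to a 2-element Windkessel (RC) model of its downstream
bed,
$$Q(t) = \frac{P - P_d}{R} + C\,\frac{d(P - P_d)}{dt},$$
with $R = 0.95$ mmHg s/cm$^3$ and $C = 1.06$ cm$^3$/mmHg shared by all
outlets, and $\delta = RC$ always derived, never stored. The downstream
(intramyocardial) pressure $P_d(t)$ is built analytically from the same RC
equation driven by an idealized aortic half-sine systolic inflow
(`downstream_pressure()`), evaluated at its periodic steady state.

**Coupling split.** Writing $y = P - P_d$, the RC equation has the exact
per-step exponential update
$$y_n = e^{-\Delta t/\delta} y_{n-1} + R\big(1 - e^{-\Delta t/\delta}\big) Q_n$$
for flow constant over the step. The outlet traction applied inside the
linear solve is therefore split as
$P_n = R(1 - e^{-\Delta t/\delta})\,Q_n + \big[e^{-\Delta t/\delta} y_{n-1} + P_d(t_n)\big]$:
the first (implicit) part multiplies the instantaneous outlet flux and
enters the system matrix as a rank-one boundary block per outlet — the
coupled-multidomain construction — while the bracket is known from stored
state. At the initial instant the accumulated flow history is zero and the
full resistance acts implicitly:
$P_0 = R\,Q_0 + (P^0 - R Q_{init} - P_d(0)) + P_d(0)$. This split
reproduces the analytic RC solution to machine precision for arbitrary
piecewise-constant flow (tested), which a split that keeps both the full
implicit $R Q_n$ *and* a convolution of $Q$ itself cannot do — by parts,
the history convolution that accompanies a full implicit resistance must
act on $dQ$, and the exponential-integrator form above is its exact
discrete equivalent.

A `free` outlet is the natural zero-traction condition; the `mixed`
assignment makes the *longest terminal branch* (greatest centreline
arclength, computed, never hard-coded) free and keeps Windkessel models on
the rest.

**The $P_d$ scale.** The amplitude of the aortic half-sine ($Q_0 = 6$
cm$^3$/s) and the baseline (2 mmHg, a left-atrial scale) are package
defaults, not literature values. They were set, before any simulation was
run, from a back-of-envelope pressure budget of the 2D model: a
per-unit-depth channel at the stated inlet speeds develops transtenotic
drops of order 1 mmHg across intermediate lesions, so the aortic-scale
pressure must sit near 5–10 mmHg for 56–68% stenoses to land in the
clinically interesting FFR band (0.7–0.9) that motivates FFR in the first
place. A 2D per-unit-depth model cannot reproduce absolute physiological
pressures (90+ mmHg aortic); what matters for the FFR ratio is the
relative scale of drop to driving pressure, and these defaults place the
packaged fixtures in that regime.

## Discretization

Taylor–Hood elements on triangles — continuous piecewise-quadratic (P2)
velocities and piecewise-linear (P1) pressures, an inf-sup stable pair —
with a 7-point degree-5 quadrature rule. Time stepping is backward Euler
(`dt = 5e-3` s by default, an exact divisor of $T_c$) with the standard
semi-implicit treatment: the Carreau viscosity is evaluated at the lagged
shear-rate field, and convection is linearized as $b(u_n, u_{n+1}, v)$;
both make each step a single sparse linear solve with no CFL restriction.
The implicit Windkessel resistance adds one rank-one block per outlet.

Internally the momentum equation is assembled in SI units (geometry is
converted from cm, tractions from mmHg at the boundary; 1 mmHg = 133.322
Pa); probe pressures are reported in mmHg and fluxes per unit depth as
cm$^3$/s under a 1 cm slab convention. FFR, a pressure ratio, is invariant
to this choice.

The sparse systems are solved by a direct LU factorization with the
fill-reducing ordering that handles the saddle-point block structure best
in practice (`Matrix::lu(order = 3)`); with Dirichlet velocities on inlet
and walls and at least one traction-type outlet the pressure level is set
by the boundary terms, and only in the degenerate all-Dirichlet case is
one pressure degree of freedom pinned to zero. The time loop caches the
assembled sparsity pattern once and refreshes only the numeric values
each step; the cached path is tested to agree with the general assembly
path to machine precision.

The initial condition is a steady Stokes solve (constant viscosity
$\mu_0$, inlet profile at $I(0)$, outlets at their initial-instant
traction), which is discretely divergence-free. Five cycles are simulated
by default so that the periodic regime is established; cycle-4 vs cycle-5
probe traces agree within a few percent on the packaged fixtures.

## Synthetic geometry

No patient geometry ships with the package (none is publicly available),
so a parametric generator emulates the study domain:

* a **tree**: straight branches joined by Y-splits; each child starts from
  one half of its parent's end cross-section and blends to its own
  diameter over about one parent diameter, producing a natural flow
  divider at the carina. The packaged left-tree fixture has a trunk, two
  intermediate branches and four terminal branches with diameters 0.26–0.40
  cm — coronary calibers, declared defaults, not measurements;
* **lesions**: smooth symmetric cosine narrowings; the degree is the
  single controlled severity variable and the throat width is exactly
  $(1-\text{degree})\,D_{ref}$. The fixture carries a 68% lesion on a
  short terminal branch (its sensor ends up 0.3 cm before the outlet —
  deliberately close to the exit) and a 56% lesion at the entrance of the
  longest branch (long run-out past the sensor);
* a **sensor disk** per lesion: diameter $D_{ref}/10$ (the 0.014-inch
  clinical wire), centred 1 cm beyond the lesion centre, meshed as a true
  obstacle whose polygonal contour (at least 8, typically 16 edges) stays
  within a few percent of the circular perimeter. Displacements along the
  flow (tangential) and across it (normal) are first-class parameters for
  the uncertainty sweeps. A degree-zero "healthy" variant anchors the
  disk at an absolute position for reference runs.

Meshing is a structured mapped-strip triangulation per branch (stations
along the centreline, a fixed even number of intervals across the lumen),
conforming across bifurcations through a 1-to-2 fan band, graded inside
stenoses and around sensors, with an O-grid annulus joining the disk
contour to the surrounding grid. Element counts grow strictly under
refinement and a quality floor aborts under-resolved geometries with a
diagnostic. Meshes round-trip through Gmsh MSH 2.2 ASCII (tags as physical
groups, probe metadata as node data); fields export to VTU.

What the fixtures do *not* emulate: real lumen irregularity and curvature,
image segmentation noise, vessel-wall compliance, out-of-plane flow, and
patient-specific outflow splits. Passing the packaged property tests shows
the *method* behaves correctly (monotone severity response, stabilized
running averages, directional boundary-condition effects), not that any
particular clinical FFR value would be reproduced.

## The FFR estimator

At every step the aortic pressure $P_a$ is the arithmetic mean of the
nodal pressures inside a virtual box of half-width 0.05 cm centred 1 cm
from the inlet along the trunk (past entrance transients, upstream of all
lesions; the box is not an obstacle and its width is configurable because
only its centre is physically pinned). The distal pressure is the mean
over the sensor-disk contour nodes. Nodal (unweighted) means mimic a
device averaging point samples; on the near-uniform contours produced by
the mesher they agree with length-weighted means to well under a percent.

Per cycle $k$, $\bar P = \frac{1}{T_c}\int p\,dt$ is computed by
left-rectangle quadrature on the `dt` grid (a device samples at its
acquisition tick; trapezoid is available and differs by $O(dt)$), the
cycle FFR is $\bar P_{distal}/\bar P_a$, and the reported value is the
running average $FFR_a(k) = \tfrac1k\sum_{j\le k} FFR_j$ — the
cumulative-mean convention, verified in the tests against reference
per-cycle tables to four decimals. Classification uses the clinical cutoffs:
below 0.75 significant, above 0.80 not significant, between them a gray
zone; sensor-sweep classifications use the single 0.75 cutoff.

## Experiment drivers and study sizes

`mesh_convergence()` re-meshes the single-lesion tree across element
sizes and tabulates per-cycle FFR and $FFR_a$ like a grid-refinement
table, with stabilization diagnostics across cycles and between the two
finest grids. Which lesion a single-lesion convergence study should carry
is not something the protocol itself fixes, so the lesion is an explicit
parameter; the packaged default is the 56% lesion.
`bc_model_grid()` crosses flow models with outlet assignments on the
two-lesion tree; `sensor_sweep()` re-meshes per sensor position (same
meshing parameters throughout, so position is the only variable) over
$\pm 3/10\,D_{ref}$ (normal) or $\pm 6/10\,D_{ref}$ (tangential), 26
positions by default; `field_comparison()` writes peak-systole and
peak-diastole VTU snapshots (the peaks are taken at $T_{sys}/2$ and the
diastolic midpoint, instants the terminology alone does not fix).

The package's own test suite runs these studies at reduced sizes chosen
to keep the full suite in the minutes range on one core: element sizes
0.085–0.13 cm (about 700–1600 vertices on the tree — the coarse end of
the grid-refinement ladder), `dt = 8` ms (100 steps per cycle), five
cycles, and 7 sweep positions per direction. The defaults
users get (`dt = 5` ms, 26 positions) match the study protocol.

One consequence of the scaled 2D conditions is worth stating: the
sensor-position sweeps on the packaged fixtures produce genuinely
non-constant FFR curves, but the within-sweep variation (of order 0.01,
set by the local dynamic pressure at cm/s flow speeds) is small compared
with the distance from the fixtures' FFR values to the 0.75 cutoff, under
either outlet model — Windkessel sweeps sit above the cutoff throughout
and free-outlet sweeps of a near-exit sensor sit far below it throughout.
So on these fixtures the sensor position perturbs the FFR *value* but not
its classification; a classification flip within a sweep requires a
geometry whose baseline FFR already sits at the cutoff knife-edge.

## Known limitations

* 2D per-unit-depth flow: absolute pressures and velocities are not
  physiological; only ratios and directional effects are meaningful.
* Straight-branch parametric trees; no patient-specific reconstruction.
* Rigid walls (no fluid–structure interaction), laminar flow, no
  turbulence closure; linearized convection may damp the strongest jets.
* The traction inlet mode interprets the waveform value as mmHg — a
  literal but dimensionally loose reading, provided for comparison runs
  only.
* First-order time accuracy (backward Euler with lagged coefficients);
  the self-convergence test verifies the observed order on the fixtures.
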