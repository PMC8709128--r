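---
title: "Degradation-aware aneurysm hemodynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degradation-aware aneurysm hemodynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuflow)
```

## The scientific question

Cerebral aneurysms grow and rupture through an interplay between wall-tissue
degradation and the hemodynamic environment. Two wall-shear metrics dominate
the rupture-risk literature: the time-averaged wall shear stress (TAWSS),
which measures the *magnitude* of the shear the endothelium feels over a
cardiac cycle, and the oscillatory shear index (OSI), which measures how much
the shear *direction* reverses. Low TAWSS combined with high OSI marks a
rupture-prone, thrombosis-prone phenotype; their ratio, the endothelial cell
activation potential (ECAP = OSI/TAWSS), condenses this into one number.

This package studies the *feedback* direction of that interplay: when the
aneurysmal wall softens through damage, how do TAWSS, OSI and ECAP change,
and where? The package provides the material model for the softening wall, a
reduced-order compliant-tube surrogate for fluid–structure interaction (FSI),
outlet boundary-condition construction, the metric stack, a paired
non-degraded/degraded comparison layer, and a synthetic-data generator with
analytic ground truth so that every stage of the pipeline can be verified
without cluster-scale 3D FSI runs.

## The wall material model

The aneurysm wall is a fiber-reinforced, nearly incompressible hyperelastic
solid with damage acting on the collagen fibers:

$$\psi = \underbrace{c_1\,(I_1 I_3^{-1/3} - 3)}_{\text{ground matrix}}
 + \underbrace{\epsilon_1\,(I_3^{\epsilon_2} + I_3^{-\epsilon_2} - 2)}_{\text{volumetric penalty}}
 + \sum_{a=1,2} (1 - D_a)\,
   \underbrace{\alpha_1 \langle E_a \rangle^{\alpha_2}}_{\text{fiber family } a},$$

with $E_a = \kappa I_1 + (1-3\kappa) I_{4,a} - 1$ the generalized
(dispersion-weighted) fiber invariant and two symmetric fiber families at
$\pm\beta_f$ from the circumferential direction in the wall tangent plane.
Fibers carry load only in tension ($\langle\cdot\rangle$ is the Macaulay
bracket) — the standard convexity and physics safeguard. Near-
incompressibility is enforced by the $\epsilon_1/\epsilon_2$ penalty rather
than a Lagrange multiplier, matching the parameter set used.

Damage per family is discontinuous (Mullins-type): it is driven by the
running maximum $\beta_a$ of the *effective* (undamaged) fiber energy, so
reloading below the historical maximum produces no new damage, and evolves
through the saturation law

$$D_a = D_\infty\left[1 - e^{-\beta_a/\gamma_\infty}\right]^{\beta_s}.$$

The default parameters (kPa where dimensional) are the published aneurysm-
wall set exposed by `aneurysm_params()`:

| parameter | value | meaning |
|---|---|---|
| $c_1$ | 9.02 | ground-matrix stiffness |
| $\epsilon_1,\ \epsilon_2$ | 499.8, 2.4 | volumetric penalty |
| $\alpha_1,\ \alpha_2$ | 1400, 2.2 | fiber stiffness and exponent |
| $\kappa$ | $10^{-8}$ | fiber dispersion (effectively aligned) |
| $\beta_f$ | 39.87° | fiber angle from circumferential |
| $D_\infty$ | 0.96 | damage saturation bound |
| $\gamma_\infty$ | 11 or 18 | damage-intensity scale |
| $\beta_s$ | 0.06 | damage shape exponent |

Two presets differ only in $\gamma_\infty$: 11 kPa (higher damage intensity)
and 18 kPa (lower). Because $\beta_a/\gamma_\infty$ enters the exponential,
a larger $\gamma_\infty$ always yields less damage under identical loading —
an ordering the test suite asserts.

**Choice of the saturation-law shape.** With the three parameters
$(D_\infty, \gamma_\infty, \beta_s)$ two natural one-line saturation laws
exist: one in which $\beta_s$ fixes the *fraction* of $D_\infty$ reached at
$\beta = \gamma_\infty$ (so damage grows roughly linearly from zero), and
the one adopted here, in which $\beta_s$ is a *shape exponent*. We evaluated
both against the physics the package must reproduce. With the
fraction-style law and the stiff published fiber parameters, fiber energies
at physiological strains are far below $\gamma_\infty$, damage stays below
one percent, and degradation has no visible effect on anything — flatly
inconsistent with a degradation study, and the thickness-sensitivity bound
of the tube experiment (below) is badly violated. With the shape-exponent
law and the small published $\beta_s = 0.06$, damage activates readily once
fibers load and then saturates almost independently of the load level; the
degradation effect is strong and insensitive to wall thickness, as reported
for this class of models. All contractual properties — $0 \le D \le
D_\infty$, irreversibility, per-cycle softening, the $\gamma_\infty$
intensity ordering — hold for either form; the choice is fixed here once
and not revisited.

The Cauchy stress is the analytic push-forward of $2\,\partial\psi/\partial
C$; the test suite verifies it against central finite differences of the
energy at relative tolerance $10^{-5}$, and against the incompressible
Neo-Hookean closed form when the fibers are removed.

`run_cyclic_protocol()` drives a material point through stretch-controlled
cycles under membrane kinematics ($F = \mathrm{diag}(\lambda, 1,
1/\lambda)$), evaluating stress *before* the damage update in each step
(explicit ordering). The first loading branch is therefore the virgin
response, and the first-cycle peak stress strictly exceeds later cycles' —
the Mullins softening signature; once the history maximum saturates, all
subsequent cycles coincide.

## The membrane-tube FSI surrogate

Full FSI on patient geometries takes days per run on a multicore machine;
the tube experiment that motivates the homogeneous-wall-thickness assumption
does not need it. `run_tube_experiment()` reduces the compliant straight
tube to a quasi-static thin-walled membrane: anchored ends (fixed axial
stretch $\lambda_z = 1$, the analogue of homogeneous Dirichlet conditions),
isochoric thinning ($\lambda_r = 1/\lambda_\theta$), and Laplace
equilibrium

$$\sigma_\theta(\lambda)\, \frac{h_0}{\lambda} = P\,\lambda\, r_0,$$

solved per load step by Brent's method to residual $10^{-10}$ (a damped
Newton solver is provided as a cross-check; both agree to $10^{-8}$).
Damage couples to the solve through a staggered fixed point — solve,
update damage, re-solve — iterated to machine-level stretch agreement;
because damage is a saturating function of the history maximum, the
iteration is contractive. Fluid inertia, axial wave propagation and bending
are deliberately outside this model.

The experiment runs the identical cyclic pressure program twice (damage
active / damage frozen) and reports the relative change in final-cycle peak
radial strain, $(\epsilon^{nd} - \epsilon^{d})/\epsilon^{nd} \times 100$.
We normalize by the non-degraded strain by default (the degraded twin
always inflates at least as much, so the default is $\le 0$); the
alternative normalization is exposed as an argument. The cyclic load is the
pulsatile waveform shape rescaled to 8.7–20 kPa, period 0.8 s, five cycles
— after the first cycle's peak the damage state is stationary, so five
cycles comfortably reach the cyclically repeating regime. Each cycle's time
grid is augmented with the exact in-cycle argmax of the pressure program,
which makes peak strains independent of the within-cycle resolution
(verified to $10^{-6}$ relative under grid halving).

`thickness_sweep()` repeats the paired experiment across wall thicknesses
(default 0.02, 0.04, 0.06 cm on the 0.41 cm tube) and reports the relative
spread $(\max - \min)/|\mathrm{mean}|$ of the degradation effect. A small
spread justifies modelling the wall with one homogeneous thickness;
`analysis/03_tube_thickness.R` computes it at 64 steps per cycle.

## Windkessel outlet boundary conditions

Each outlet carries a three-element Windkessel: proximal resistance $R_p$
in series with parallel distal resistance $R_d$ and capacitance $C$ (CGS
units throughout). The split is $R_d = k_d R_{tot}$, $R_p = (1-k_d)
R_{tot}$ with $k_d = 0.9$ by default, conservation being exact by
construction. Across a bifurcation, per-outlet flow shares follow a
diameter power law; the exponent is configurable with default 3 (Murray's
law), and the per-outlet resistances are chosen so the parallel network
reproduces both the split and the intended net resistance.

`integrate_pressure()` integrates $C\,\dot P_{dist} = Q - P_{dist}/R_d$,
$P = P_{dist} + Q R_p$ by the implicit trapezoid rule *on the waveform's
sample grid* (A-stable for stiff $R C$ combinations, and grid-tied so
reruns are bit-reproducible), repeating cycles until the trace is periodic
(cycle-to-cycle change below 0.1 mmHg) and returning the last cycle — the
same discard-the-transient convention the metric stack assumes. The
reported node is the proximal (inlet-side) pressure. On sinusoidal inflow
the integrator matches the closed-form periodic solution of the linear ODE
to well under 0.5%.

`tune_windkessel()` exploits two structural facts: in the periodic state
the mean pressure is *exactly* $\bar Q\,(R_p + R_d)$, giving $R_{tot}$ in
closed form from the target mean (default mean: diastolic + pulse/3); and
the pulse amplitude is monotone in $C$ (low capacitance, high amplitude),
so a 1-D derivative-free search on $\log_{10} C$ fits systole and
diastole. Targets of 90/160 and 70/140 mmHg round-trip within 2 mmHg on
the mean and 5 mmHg on the extremes. A zero-pulse target makes $C$
unidentifiable; the tuner flags `C_unbounded` and fits the mean alone.

## The metric stack and its degenerate cases

With $\tau_w(x, t)$ the wall-shear vector over one post-transient cycle of
duration $T$:

$$\mathrm{TAWSS} = \frac{1}{T}\int_0^T |\tau_w|\,dt, \qquad
\mathrm{OSI} = \frac{1}{2}\left(1 -
  \frac{|\int_0^T \tau_w\,dt|}{T\cdot\mathrm{TAWSS}}\right), \qquad
\mathrm{ECAP} = \frac{\mathrm{OSI}}{\mathrm{TAWSS}}.$$

Quadrature is cyclic trapezoid with wrap-around closure (the weights sum to
$T$ exactly), which makes both metrics invariant to the cycle's starting
phase and exact for piecewise-constant constructions. OSI is 0 for any
uni-directional profile and 0.5 for a symmetric 180° reversal; a square
wave reversed for the last $k$ of $n$ uniform samples has OSI $= k/n$
exactly, which the generator exploits.

Division-by-zero policy: nodes whose TAWSS falls below a floor (default
$10^{-6}$ dyn/cm²) have *undefined* OSI and ECAP — explicit `NA`, never 0
or infinity — and that mask is conserved through every downstream map
(relative changes, correlation product, digitization, regime labels).
Clipping of OSI against round-off is logged in an attribute. Warm-up is the
caller's duty: the series handed to the metrics must already be the
post-transient cycle.

## The comparison layer

For any per-node field $f$, the degradation response is the relative
percentage change $\Delta f = (f^d - f^{nd})/f^{nd} \times 100$. The
TAWSS–OSI coupling is quantified by the correlation product

$$C = \frac{\Delta \mathrm{TAWSS}}{100}\cdot\frac{\Delta
\mathrm{OSI}}{100}\times 100,$$

read as the product of fractional changes rescaled to percent — the reading
under which a ±5% digitization threshold is dimensionally meaningful.
Digitization maps $|C| > 5$ to $\mathrm{sign}(C)$ and keeps an explicit 0
class for sub-threshold nodes (lossless; the threshold is configurable).
All "high" classifications are strict inequalities — TAWSS > 25 dyn/cm²,
OSI > 0.15, $|C| > 5\%$ — so boundary values classify "low"/0; the
convention is documented here and in the function contracts. Whether the
±5% threshold should instead apply to each $\Delta$ separately is left
configurable through the threshold argument structure; the product reading
is the default. Comparisons are restricted to the dome (aneurysm-labelled)
region by default, where the degradation acts; full-mesh mode is available.

`inverse_correlation_report()` summarizes the signature of interest: the
fraction of digitized-nonzero nodes with $C = -1$ (TAWSS and OSI moved
oppositely), overall and per regime, plus the mean ECAP change in the
low-TAWSS/high-OSI corner. Empty regimes are reported absent, not zero.

## What the synthetic generator emulates — and what it does not

`make_paired_wss_series()` emulates the *output* of an FSI run, not the
physics: an impingement patch of high, near-unidirectional shear
(40 dyn/cm², OSI 0.05 by default) and a surrounding low, oscillatory region
(8 dyn/cm², OSI 0.25), on a dome-and-parent mesh with the idealized
dimensions (1.0 cm sac, 0.41 cm vessel; the 60° branch angle of the
reference geometry is noted but plays no role in any surrogate
computation). Degradation is applied as a multiplicative TAWSS scaling and
a reversal-fraction shift of OSI, localized to the low-shear region with
opposite signs by default (−20% TAWSS, +30% OSI) and same-signed shifts
(+25%/+25%) in the impingement patch — the spatial pattern the comparison
layer is designed to detect. OSI shifts are quantized to the sample grid
and the *applied* per-node effects are returned as ground truth, so
noise-free recovery is exact rather than approximate. Patch indicators are
sharp (binary) for the same reason. Seeded Gaussian noise is available for
robustness tests; runs are bit-for-bit reproducible under a fixed seed.

Passing recovery tests therefore demonstrates that the metric and
comparison stack measures what it claims on fields with known structure. It
does *not* demonstrate CFD fidelity: real WSS fields have continuous
spatial gradients, waveform-locked phase structure, and degradation
responses that emerge from wall–flow coupling rather than being painted on.
Those belong to a 3D FSI solver, which is out of scope here.

## Numerical choices and problem sizes

- Internal units are CGS (stress dyn/cm², 1 kPa = 10⁴ dyn/cm², 1 mmHg =
  1333.22 dyn/cm²) with exact-factor conversion at the boundaries
  (`convert_units()`), because published Windkessel constants are CGS while
  material data are kPa and pressures mmHg.
- Tube equilibrium: Brent on $[1 + 10^{-12}, 3]$, tolerance $10^{-14}$ on
  the stretch; divergence (no root below stretch 3) is reported with the
  offending load.
- Default problem sizes keep every analysis on one CPU in seconds to a
  minute: 64 time steps per cycle and 5 cycles for tube runs, 80 samples
  per cycle for synthetic series, mesh resolution 24–32 (600–1000 nodes),
  2000-sample grids where an ODE integration is compared against a closed
  form.
- The time-step bookkeeping helper `steps_per_cycle()` records the solver
  resolution a full FSI run would use (8000 steps for $T = 0.8$ s at
  $\Delta t = 10^{-4}$ s) in pipeline provenance.

## Known limitations

Active response and fatigue of the wall are not modelled; fiber orientation
is idealized (two symmetric families); the tube surrogate has no fluid
inertia; the Windkessel tuner fits mean and pulse with two degrees of
freedom, so waveforms whose shape is very different from a systolic-bump
inflow may not reach both extreme targets; and the synthetic fields, while
structurally faithful, are not CFD. The package is built for qualitative,
mechanism-level conclusions — the inverse TAWSS/OSI response to
degradation and its localization to low-shear regions — not for
patient-specific prediction.
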