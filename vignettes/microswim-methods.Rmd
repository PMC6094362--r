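---
title: "Predicting microswimmer performance: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting microswimmer performance: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microswim)
```

## The swimming problem

The package models a bacterium-like robotic swimmer: a rigid spherical head
of radius $R$ driven by a rigid circular helix (amplitude $b$, pitch
$\lambda$, $N_\lambda$ turns, cross-section radius $r$) rotating about the
common $x$ axis at the prescribed motor rate
$\omega = \Omega_{head} - \Omega_{flagellum}$.  At micrometre scales inertia
is negligible and the flow obeys the Stokes equations, so forces depend
linearly on velocities through resistance matrices, and self-propulsion is
expressed by two balance laws: the net viscous force and torque on the
swimmer vanish.  Solving the axial force/torque balance for the unknown
swimming speed $U$ and head rotation rate $\Omega$ is the core computation;
everything else (efficiencies, optimal lengths) derives from it.

Three levels of hydrodynamic fidelity are implemented:

* **Resistive force theory (RFT)** — local drag: a filament element feels
  $df = [C_T \hat t \hat t + C_N (I - \hat t\hat t)]\,u\,ds$.  Two standard
  coefficient pairs are provided (`drag_coefficients`): the classical
  Gray–Hancock pair with reference length $q = \lambda$,
  $C_T = 2\pi\mu/(\ln(2q/r) - 1/2)$, $C_N = 4\pi\mu/(\ln(2q/r) + 1/2)$, and
  Lighthill's replacement pair with $q = 0.09\lambda$,
  $C_T = 2\pi\mu/\ln(2q/r)$, $C_N = 4\pi\mu/(\ln(2q/r) + 1/2)$.  A variant
  with the half-integer terms swapped between the two Gray–Hancock
  denominators circulates in parts of the literature; it is available via
  `swap_half = TRUE` but markedly overestimates the normal-to-tangential
  anisotropy, and the classical pair is what the standard helical-propulsion
  simulators use, so the classical placement is the default.
* **Additive approximation (AA)** — Purcell's recipe: the assembly's
  resistance is the sum of the head's closed forms ($A_0 = 6\pi\mu R$,
  $C_0 = 8\pi\mu R^3$) and the *isolated* flagellum scalars $A, B, C$,
  giving $U = C_0 B \omega / ((C_0+C)(A_0+A) - B^2)$ (`solve_additive`).
  Hydrodynamic interactions between head and tail are ignored.
* **Global approach (GA)** — the coupled problem: partwise resistance
  blocks $\mathcal R_1, \mathcal R_2$ (force/torque on the *whole* assembly
  induced by unit motions of one part with the other held fixed,
  `partwise_resistance`) replace the isolated scalars; their sum is the true
  assembly resistance, symmetric and positive definite, although the
  summands are not individually symmetric.  `solve_global` solves the
  resulting axial $2\times 2$ system and cross-checks it against the
  eliminated closed form.

Because a translating body's disturbance decays like a Stokeslet ($1/d$)
while a rotating body's decays like a rotlet ($1/d^2$), the additive
approximation overestimates translational drag strongly (screening) but
rotational resistance only mildly.  This asymmetry is what the geometric
correcting factor
$$\upsilon = \frac{(A_0 + A)(B_1 + B_2)}{(A_1 + A_2)\,B}$$
exploits (`correction_factor`): multiplying the AA speed by $\upsilon$
recovers most of the interaction physics from a single coupled solve, and
the same $\upsilon$ corrects RFT predictions (speeds by $\upsilon$,
energetic efficiencies by $\upsilon^2$, work per distance by $1/\upsilon$).

## Numerical method

The coupled solver is a regularized-Stokeslet collocation method: the
velocity induced by a concentrated regularized force is finite everywhere,
so a dense linear system maps nodal force densities to nodal velocities and
is solved by direct LU factorization (deterministic, no iterative
tolerances).  Design choices that matter:

* **Head**: a Fibonacci (golden-angle) surface layout with equal area
  weights — deterministic and quasi-uniform at any node count.  The blob
  size is $c\,\sqrt{4\pi R^2/n}$, with $c = 0.3415$ fixed once by
  `calibrate_head_eps_factor(600)`: the root at which the signed errors of
  the computed drag (vs $6\pi\mu R$) and rotational resistance (vs
  $8\pi\mu R^3$) cancel.  Calibrating on drag alone would leave the
  rotational resistance about $1.5\%$ high; at the balanced root both are
  within $0.7\%$ for 300–1200 nodes and the constant is scale invariant.
* **Flagellum**: a centerline distribution, one collocation node per panel
  (midpoint rule along the analytic curve), blob size equal to the
  cross-section radius $r$.  Because the panel length exceeds the blob
  size, the single-layer integral over each panel is evaluated by
  sub-quadrature at spacing $\approx \varepsilon/2$ (the density is
  panel-wise constant); without this the coefficients do not converge in
  the node count.  A centerline model with $\varepsilon = r$ behaves
  slightly thinner than a no-slip cylinder of radius $r$: against a
  tube-surface discretization of the same helix (and against the
  finite-cylinder drag formulas of Tirado and García de la Torre, which the
  tube method reproduces to $0.6\%$) it understates the axial drag by
  $\approx 8\%$ and the rotational coefficient by $\approx 13\%$.
  `calibrate_filament_eps_factor` provides the cylinder-matched blob factor
  ($\kappa \approx 1.64 \approx e^{1/2}$) for applications that need
  quantitative cylinder fidelity; the package default stays at
  $\varepsilon = r$, which also tracks the reference boundary-element
  results for the composite swimmer more closely (coarse singular-BEM tube
  meshes under-resolve the filament in a similar measure).
* **Attachment**: the helix axis is the $x$ axis through the head center
  and the centerline starts at $x_0 = R + g$ (gap $g = 0$ by default).  An
  optional amplitude envelope $E(x) = 1 - e^{-(k_E x)^2}$ brings a tapered
  tail onto the axis at the junction; the printed studies use the plain
  (untapered) helix, since the reference length sweeps are defined on the
  ideal circular helix.
* **Stroke averaging**: resistance coefficients can be averaged over
  $n_{phase}$ equally spaced helix phases.  For whole-turn helices the
  axial scalars are phase independent to quadrature accuracy (the phase
  rotation is an exact conjugation of the discrete system), so the default
  is $n_{phase} = 1$; averaging over 8 phases annihilates the first and
  second angular harmonics exactly and is used to verify the
  rotational-symmetry zero pattern of the helix matrix.
* **Pole convention**: head center for assembly matrices.  All axial
  scalars used by the theory are invariant to shifting the pole along the
  axis, so the choice is cosmetic for force-free swimming.
* **Motor torque**: in the additive path from the head torque balance
  $T = C_0\,\Omega$; in the global path by integrating the axial torque of
  the solved tractions over the flagellum nodes.  The two definitions
  coincide within their respective models.

`solve_free_swimming` implements the general phase-resolved path: the
collocation equations are augmented with six zero-force/zero-torque
constraints and solved for the instantaneous rigid motion given any nodal
gait velocity.  For the robotic swimmer its phase-averaged axial speed
agrees with the stroke-averaged $2\times2$ solve within $2\%$ (the small
difference is the transverse wobble that the axial formulation suppresses);
trajectories are integrated with the exponential map for orientation and a
midpoint rule for position (`integrate_trajectory`).

## Validation and known limitations

The benchmark suite (`benchmark_suite`) regenerates every validation case
from scratch: Stokes drag and rotational resistance of a sphere (closed
forms), two translating spheres against both the far-field
method-of-reflections estimate and the exact bispherical-coordinate series
(`two_sphere_exact`), the stroke-averaged helix zero pattern, RFT helix
coefficients against their closed forms, and the model-comparison errors
for the reference two-turn swimmer.

Two caveats discovered during validation are worth recording.  First, the
far-field reflections estimate $1/(1 + 3R/2\rho - (R/\rho)^3)$ is itself
about $4\%$ from the exact bispherical solution at the closest benchmark
separation $\rho = 2.2R$ (the multipole expansion is at its validity edge
there), while the solver stays within $0.4\%$ of the exact series at all
separations; comparisons with the reflections estimate are therefore
meaningful only from $\rho \gtrsim 3R$.  Second, per-sphere drag *rises*
monotonically toward the isolated value as the separation grows — the
quantity that decays with separation is the interaction (screening) term.

For the composite swimmer the additive approximation's speed error changes
sign near $N_\lambda \approx 6$ for the pitch-$2.42b$ family (overestimate
for short tails, settling at an underestimate of $\approx 8\%$ for long
ones, consistent with $\upsilon$ rising through 1).  In a neighborhood of
that crossing the uncorrected error passes through zero, so no multiplicative
correction can beat it pointwise there; the corrected speed is more accurate
everywhere the additive error is substantial.  Users comparing correction
strategies should compare error *curves*, not single lengths.

The synthetic geometries are ideal: rigid parts, perfect helix, spherical
head, free space.  Passing tests therefore demonstrate the solver and the
theory on the model system, not agreement with any particular experimental
swimmer (flexible hooks, bundling, walls and Brownian effects are all
outside scope, as are image systems for no-slip walls).

## Study configurations and problem sizes

The documented studies use the nondimensional system $\mu = b = \omega = 1$.
The reference comparison geometry is the two-turn helix $r = b/16$,
$\lambda = 8b$ with head $R = 2b$; length sweeps use the $\lambda = 2.42b$,
$r = b/16$ family with the same head ($R = 2b$, matching the reference
configuration; the sweep's head size is a package choice).  Default
resolutions — 32 flagellum panels per turn and 600 head nodes — were chosen
so that the sphere calibration holds to better than $1\%$ and doubling
either count changes the axial helix coefficients by less than $1\%$.  A
single configuration solves in a few seconds; a ten-point length sweep with
all methods takes under a minute on one core.

## Efficiency measures

Six performance measures are computed (`efficiencies`), each in a global
variant (from the solved $U$, $\Omega$, $T_{motor}$), an additive closed
form, and a $\upsilon$-corrected variant: two energetic efficiencies
(useful power from dragging the head alone, $A_0U^2/T\omega$, or the whole
swimmer, $(A_1{+}A_2)U^2/T\omega$), two propulsion efficiencies (distance
per flagellar revolution $U/(\omega-\Omega)$ and per motor revolution
$U/\omega$), the swimming efficiency $U/T\omega$ (distance per unit work)
and its reciprocal, the work per traveled distance.  Only the energetic
pair is dimensionless; the global energetic efficiencies lie in $(0, 1]$.
`optimize_length` scans a turn-count grid and refines interior maxima by
golden-section/Brent search; monotone metrics return the bracket boundary
with an explicit flag.  The global approach exhibits interior optima of the
swimming speed and of the energetic efficiency at intermediate tail
lengths; the additive approximation misses the energetic optimum entirely
(its variant is monotone), and the $\upsilon^2$ correction restores it —
the central design-relevant consequence of head–tail interactions.
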