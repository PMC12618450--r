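---
title: "Models and methods behind hygrobone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hygrobone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hygrobone)
```

This vignette is the package's own account of its models: what is being
solved, which constants matter, which choices were genuinely open and how
they were made, and what the synthetic test bed can and cannot say about
real bone.

## The physical problem

A cylindrical anchor made of a cross-linked MMA/AA co-polymer is
press-fitted into a drilled defect in trabecular bone.  On contact with
interstitial fluid the polymer swells.  Constrained by the surrounding
bone, the swelling produces compressive radial pressure at the interface
and tensile hoop stress in the bone.  Two consequences are modeled:

1. **Fixation.**  The interface pressure resists axial push-out through
   Coulomb friction, `F = mu * sum(max(p, 0) * A)` with `mu = 0.4`.
2. **Remodeling.**  The stress field is a mechanical stimulus.  Bone
   apposes where the stimulus moderately exceeds its homeostatic
   reference, does nothing inside a dead band ("lazy zone"), resorbs
   under disuse, and — crucially — also resorbs under *overload*, which
   is what makes an excessive swelling ratio counterproductive.

## Hygroscopic swelling as an eigenstrain

Swelling is modeled as a stress-free isotropic eigenstrain
`eps_hs = beta_h * (alpha_m - alpha_m,ref) * s`, where `beta_h` (m³/kg)
and the moisture concentration change (kg/m³) are measured per
composition in free-swelling immersion experiments, and `s` in [0, 1] is
a saturation scale.  The characterised compositions are

| composition | beta_h | d_alpha | linear strain |
|---|---|---|---|
| 80/20 | 1.2287 | 0.1881   | 0.23112 |
| 85/15 | 0.9920 | 0.08672  | 0.08603 |
| 90/10 | 0.9032 | 0.0487   | 0.04399 |

Swelling is applied as a steady state, not a diffusion transient: uptake
completes over weeks while remodeling spans a much longer horizon, so the
interface load is effectively constant during remodeling.  Transient
Fickian uptake, viscoelastic relaxation and anisotropic swelling are out
of scope.  The free-swelling closed form `Delta_d = d0 * beta * d_alpha`
doubles as an exact patch test for the solver: an unconstrained body
loaded by a uniform eigenstrain must develop exactly that strain with
zero stress and zero strain energy, and does so to machine precision
(`run_free_swelling()`).

## Material calibration and units

Apparent density and modulus are linear in the CT value:
`rho[g/m³] = 1041395 + 1017 * HU` and `E[Pa] = -388.8 + 5925 * rho[g/m³]`.
The package converts both at the calibration boundary into one canonical
unit system — length mm, force N, stress MPa, density g/cm³ — in which
strain energy density `U = sigma : eps / 2` comes out in J/cm³ and the
stimulus `S = U / rho` is numerically J/g with no hidden factors, so the
reference stimulus `k = 0.004 J/g` is usable directly.  A dedicated unit
test asserts this audit.  Densities are clamped to the remodeling bounds
`[0.01, 2] g/cm³` already at mapping time so that initial and evolved
states share one invariant; the modulus at the floor (59.25 MPa) is kept
rather than deleting elements, which avoids re-meshing and retains a
conservative load path through resorbed tissue.

Discrete 10-type material binning (`bin_materials`) reproduces the
classical workflow; continuous per-element properties are the default.

## The voxel finite element solver

The mesh is one bilinear quadrilateral (2D) or trilinear hexahedron (3D)
per active voxel — the standard micro-CT FE idiom — with per-element
modulus and a shared Poisson ratio.  This replaces boundary-conforming
quadratic tetrahedra deliberately: it is meshing-free, desk-scale, and
its staircase error is quantified against an analytic oracle (below).
The element stiffness for a cube scales linearly with E at fixed nu, so
assembly reduces to scaling one reference matrix, and repeated solves
reuse the cached symbolic Cholesky factorisation (the sparsity pattern
never changes during remodeling).

Choices worth recording:

* **Elastic strain in the energy.**  `U = 1/2 sigma : (eps - eps_hs)`,
  so free swelling is energy-free.  The alternative reading (total
  strain) would make an unconstrained swollen body carry spurious
  stimulus; the elastic-strain reading is the thermo-elastic analogy's
  standard form and is what the patch test pins down.
* **Tied bone–anchor interface.**  Swelling keeps the interface in
  compression, so a tied (shared-node) mesh transfers normal pressure
  like closed frictional contact; friction enters only the push-out
  integral.  Sliding contact is out of scope.
* **Interface pressure on a staircase.**  The facet traction is
  evaluated as `-n · sigma · n` with `n` the *radial* normal of the
  nominal cylinder, averaging the stresses of the two facet-adjacent
  elements.  The normal traction is continuous across a tied interface,
  and the single-side constant-strain stresses carry opposite-signed
  O(1) staircase oscillations (bone side about -27%, anchor side about
  +24% against the shrink-fit oracle at h = 0.125 mm) while their mean
  converges O(h) (about -2% at h = 0.125 mm).  Single-side estimates
  remain available via the `side` argument.
* **Verification.**  A two-material disc (swelling core, free annulus)
  has the plane-stress Lamé shrink-fit pressure as a closed form
  (`lame_shrinkfit_oracle`); the voxel FE mean interface pressure agrees
  within 5% on a 128² grid, and successive refinements differ by < 5%.
* **2D modes.**  Plane stress and plane strain are both available; the
  2D demos use plane stress, whose in-plane eigenstrain response matches
  the isotropic closed forms directly.  Plane-strain swelling uses the
  standard `(1+nu) eps0` in-plane reduction.

## The remodeling law and its integration

The rate law (defaults `B = 1`, `D = 60`, `k = 0.004 J/g`,
`delta = 0.10`) has an apposition branch `B x - D x²`,
`x = S - (1+delta)k`, whose landmarks are closed forms used in tests:
peak at `S = (1+delta)k + B/(2D) = 0.0127333` with rate
`B²/(4D) = 0.0041667`, and a zero-crossing (onset of net overload
resorption) at `(1+delta)k + B/D = 0.0210667`.  Setting `D = 0` recovers
the linear law.  Lazy-zone boundaries are inclusive (zero rate exactly at
`(1±delta)k`), removing a measure-zero ambiguity.

Forward Euler with `dt = 0.01` and clamping integrates the law.  Time is
the dimensionless unit the constants imply; no physiological calendar is
claimed.  Three single-element reductions serve as oracles: constant
stimulus (linear trajectory to an absorbing bound, with a closed-form
step count), frozen strain energy (equilibrium at `rho = U/((1+delta)k)`
when interior, e.g. `U = 0.008 J/cm³ -> rho = 1.8182 g/cm³`), and
step-halving (dt vs dt/100 trajectories agree within 0.1%).

### The coupled loop

Each checkpoint solves the FE problem, freezes the stimulus for
`resolve_every = 100` Euler steps (one time unit; the rate depends only
on S, so the clamped block update is exact), refreshes each element's
modulus from its new density, and re-solves.  Whether the original
workflow re-solved per step or per block is not determinable from its
description; `resolve_every` is the explicit knob covering both readings.

The printed 2% homeostasis criterion cannot bind per Euler step (per-step
changes are ~0.005%), so convergence is measured over a trailing window
of `check_horizon = 10` checkpoints: the run stops when the maximum
relative density change over that window is below `convergence_tol =
0.02`, or earlier when every element is at a bound or inside the lazy
zone.  Ten time units is long enough that the slowest active branch
(disuse at rate ~0.0036/unit) cannot masquerade as converged, and short
enough not to inflate run times.  `max_steps` caps the run and returns a
partial history flagged `converged = FALSE`.

### The homeostatic baseline stimulus

`remodeling_params` includes `s_baseline` (default 0), added to the
mechanical stimulus in coupled runs.  The reference `k` is defined as the
stimulus of bone under *normal physiological loading*; a model whose only
load is the anchor's swelling has far-field stimulus orders of magnitude
below `k`, which puts the entire domain in disuse by construction and
drains it to the floor — an artifact of the missing background load, not
a prediction.  The packaged demo therefore sets `s_baseline = k`:
unperturbed bone sits in the lazy zone, and only the swelling-induced
stimulus shifts the balance.  With the default `s_baseline = 0` the
package retains the textbook behavior (an unloaded block resorbs to the
floor), which the tests also assert.

## The synthetic test bed

`generate_trabecular_image` smooths Gaussian white noise with an
isotropic kernel of width `correlation_length` and thresholds at the
empirical quantile that realises the target bone volume ratio (defaults:
BVR 0.47, matching far-field ovine lumbar trabecular bone; voxel 0.25 mm
to keep FE problems desk-scale — real scans are ~24 µm).  No quantitative
trabecular correlation length was available to emulate; 0.6 mm is a free
choice giving strut widths of 2–3 voxels at the default resolution, and
is documented as such.  Bone voxels get HU on a linear ramp with erosion
distance from the void phase (strut cores read denser), giving a
non-trivial histogram for the 10-type mapping.  All randomness flows
through an explicit seed; the caller's RNG stream is restored.

What the generator does *not* emulate: scanner physics (beam hardening,
noise spectra, partial volume), anisotropic fabric, plate-like
architecture, cortical shell.  Passing tests on this bed therefore show
correctness of the pipeline's mechanics and statistics, not fidelity to
any particular specimen.

The demo geometry mirrors the in vivo protocol at desk scale: an 8 mm
press-fit defect (anchor diameter = drill diameter) in a Ø20 mm disc
(~5000 elements), outer rim fixed — justified in the source experiments
by the negligible displacement there under physiological load.  Marrow
voxels are meshed with their HU-calibrated properties, mirroring the
gap-filled ("Smart-Fill") workflow in which filled space compensates
through calibrated heterogeneous properties and remodels like bone.  An
alternative in which pore space starts near the density floor was
explored and rejected: under the quadratic overload law an element near
the floor has `S = U/rho` beyond the overload zero-crossing for any
appreciable strain, so pores could never ossify.

### The swollen anchor modulus

No stiffness is published for the swollen co-polymer, so `E_anchor` is a
free parameter (config-exposed).  The default, 75 MPa, is the package's
one calibrated choice: the swollen (hydrated, plasticised) polymer is
orders of magnitude softer than dry glassy PMMA (~2.5 GPa), and a glassy
value would push every composition's interface stimulus 10–100x beyond
the overload crossing, collapsing the composition contrast entirely.  At
75 MPa the three printed compositions land in the three regimes the
remodeling law distinguishes — 90/10 marginal, 85/15 densifying without
overload, 80/20 overloading — which is the behavior the law's own rate
curve implies for a 1 : 1.96 : 5.25 swelling-dose ratio.  Poisson ratios
are likewise unpublished; 0.3 is used for bone and anchor alike.

## Morphometry and push-out

The remodeled density field is projected back to HU by inverting the
linear calibration, then analysed exactly like a scan: a 2-mm hollow
cylinder at the interface versus an equal-volume far-field sphere, HU
band 200–1000, ratios compared by a classical paired t-test (degenerate
zero-variance pairs resolved by the t statistic's limit).  In the 2D demo
an equal-volume far disc cannot both avoid the interface shell and stay
inside the 20 mm domain, so the far ROI is volume-capped to fit; the
interface-vs-far comparison is unaffected.  ROI membership is voxel-center
based with half-open radial intervals (no double counting).

Push-out is a Coulomb integral over the interface facets, not an explicit
sliding simulation; consequently only *relative* pre/post changes are
meaningful, and the absolute forces (per mm thickness in 2D) are not
comparable to experimental newton values.  The integral is linear in mu
and in any uniform pressure scale and invariant to facet subdivision,
which the tests assert.

## Problem sizes and run times

Test and demo sizes were chosen so the whole suite runs comfortably on a
laptop core: the Lamé verification uses a 128² grid (~2 s), the BVR
recovery a 64³ image, and the three-composition demo ~5000 elements with
a few hundred checkpoints each (~1 minute total).  The acceptance script
integrates four single-element trajectories (~10⁶ Euler steps, seconds).

## Known limitations

* Linear isotropic elasticity and swelling; no contact separation, no
  geometric nonlinearity.
* The remodeling constants stem from human femur studies; applying them
  to (synthetic) ovine vertebral geometry is a modeling convention, and
  absolute densities should be read comparatively.
* 2D plane-stress demos concentrate stress differently from 3D; the 3D
  path is provided but the packaged demo is 2D for run-time reasons.
* The far-field behavior depends on the baseline-stimulus convention
  (see above); only interface-vs-far contrasts are meaningful.
* Checkerboard-prone density patterns, a known property of
  element-local SED remodeling, are not regularised (no nodal averaging
  of the stimulus).
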