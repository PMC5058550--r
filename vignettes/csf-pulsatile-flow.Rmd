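---
title: "Pulsatile CSF flow at desk scale: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulsatile CSF flow at desk scale: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(csfflow)
```

## The physical problem

Cerebrospinal fluid oscillates through the craniospinal subarachnoid space
(SAS) with the cardiac cycle: during systole, arterial inflow into the rigid
cranium displaces CSF caudally through the foramen magnum; during diastole the
flow reverses. In Chiari I malformation the tonsillar herniation narrows this
passage, and the clinical literature associates the obstruction with elevated
peak velocities, flow jets, synchronous bidirectional flow, larger
pressure drops and altered pressure/flow timing.

`csfflow` models this system at desk scale. CSF is treated as a Newtonian,
water-like fluid (density 1000 kg/m³, dynamic viscosity 7.0·10⁻⁴ Pa·s at body
temperature) in rigid-walled, idealized geometries, driven by periodic
volumetric flux waveforms of the kind PC-MRI measures at the cervical SAS and
in the aqueduct. All the hydrodynamic measures the package reports — pressure
drops, gradients, resistances, phase differences, regional peak velocities,
bidirectional-flow fractions — are computed from these simulations exactly as
they would be from patient-specific runs.

## Flux waveforms

PC-MRI yields ~32 flux samples per cardiac cycle. The solver needs boundary
values at a far finer time resolution, so samples are interpolated by a cubic
spline with **periodic** end conditions (`fit_periodic_spline()`). Periodic
(rather than natural or clamped) ends are a deliberate choice: the cardiac
cycle wraps, and a C² seam avoids a spurious kink in the time derivative of
the boundary forcing, which enters the momentum balance directly. Interpolated
waveforms reproduce every sample exactly and are 4th-order accurate on
band-limited signals (both properties are tested).

All cycle statistics are measured on a dense grid (4096 points/cycle) of the
spline, never on the raw samples, after shifting the time origin to cervical
flow reversal (`align_cycle_origin()`; negative flux = caudal = systolic).
Peak and crossing locations are refined by bisection to 10⁻⁶ of the period;
when a noisy waveform has several systolic minima, the global minimum wins,
with ties broken by earliest time.

## The synthetic-waveform generator

No sample tables for real subjects are bundled — the generator targets the
*published summary statistics* that characterize each subject instead, which
are the only quantitative anchors available for waveform shape:

| preset | heart rate | caudal fraction | systolic peak | aqueduct delay |
|---|---|---|---|---|
| CON1 | 71 bpm | 26 % | 8 % | 28 % |
| P1 | 86 bpm | 47 % | 17.5 % | 15 % |
| P2 | 77 bpm | 37 % | 14 % | 16 % |

`make_waveform()` builds a truncated Fourier series (12 harmonics by default,
below the 16-harmonic Nyquist limit of 32 samples/cycle) by least-squares
projection of an asymmetric two-lobe target shape, then iterates the shape
parameters deterministically until the dense-grid caudal fraction and peak
time match the preset to within 0.002 of a cycle; the amplitude is then scaled
exactly and the mean is exactly the configured net flow (default 0 for a
rigid domain). Infeasible target sets (e.g. a 99 % caudal fraction with two
harmonics) fail with the violated target named. Aqueduct waveforms are
time-shifted, amplitude-scaled copies of the cervical waveform
(`make_aqueduct_pair()`), with the delay expressed as a cycle fraction and a
default flux ratio of 0.10 — roughly a tenth of the CSF flow below the foramen
magnum originates in the ventricular system.

Amplitudes are not published as tables, so the defaults (4000/3000/5000 mm³/s
cervical) were chosen once so that peak velocities in the idealized geometries
land in the physiological 10–100 mm/s range; they are preset fields, not
hard-coded. Optional Gaussian sample noise (`noise_snr`) uses the preset seed
through an RNG-state-preserving wrapper, so noise-free generation is
seed-independent and the caller's RNG stream is never disturbed.

What the generator does *not* emulate: velocity aliasing and V_enc effects,
beat-to-beat variability, measurement bias near vessel walls, or the true
curve shapes of any individual. Passing tests therefore demonstrate that the
pipeline treats waveforms with realistic timing structure correctly — not that
it reproduces any particular subject.

## Geometries

Three idealizations stand in for segmented anatomy:

* **plane channel** — the verification geometry; Poiseuille and oscillatory
  closed forms exist.
* **axisymmetric annulus** (default solver geometry; the SAS is annular):
  cord radius 4 mm, dura radius 7 mm, length 60 mm, with an optional stenosis
  narrowing the gap from the inner wall. The stenosis profile is a cosine
  bump (C¹), avoiding the pressure spikes a slope discontinuity would inject;
  the shipped `annulus_stenosed` preset occludes 60 % of the gap over 20 mm.
* **branched two-inlet** planar domain with the craniospinal topology:
  cervical SAS below, a constriction at the foramen-magnum level, a pontine
  cistern above, and a side arm for the aqueduct. The flux split between
  unmeasured inlets is exposed as a parameter (scaled by area by default)
  rather than guessed.

Mapped kinds use a boundary-fitted, column-stretched grid
r(z, η) = Rin(z) + η·gap(z), so the stenosis wall is *resolution-independent*
— mesh-convergence metrics then measure scheme convergence, not stair-step
geometry noise. The branched kind keeps an identity mapping and realizes its
walls as an axis-aligned solid-cell mask, which also puts every wall on a grid
line at every resolution.

## The flow solver

The incompressible Navier–Stokes equations are discretized on a staggered
(MAC) grid — velocity components on faces, pressure at cell centres — in 2-D
planar or axisymmetric coordinates. This is deliberately not a 3-D
finite-element patient-mesh solver: the governing equations and every reported
measure are discretization-agnostic, and the structured grid admits analytic
oracles and exact conservation statements. Axisymmetric operators carry the
1/r metric terms (r = 0 never occurs in the annulus); mapped grids compose
physical derivatives by the chain rule, with all metric coefficients taken
from the closed-form stenosis profile.

Time stepping is the standard (non-rotational) **incremental
pressure-correction scheme**:

1. *Tentative velocity*: viscous terms implicit (backward Euler), convection
   explicit — 2nd-order central differences integrated with a two-step
   Adams–Bashforth extrapolation — under the previous pressure gradient.
   Plain forward Euler with central convection is linearly unstable in the
   convection-dominated limit; AB2 with the viscous damping present here is
   the classic stable pairing for MAC codes. An advective CFL guard aborts
   with advice if the step is too large.
2. *Pressure increment*: a Poisson solve with homogeneous Neumann conditions
   on all boundaries. The discrete operator is the exact matrix product of
   the divergence and gradient operators, so the subsequent projection zeroes
   the divergence to solver precision.
3. *Projection* of the velocity and incremental pressure update.

The divergence is assembled in conservative, volume-integrated form with the
exact slanted-face fluxes of the mapped cells. Two structural identities
follow and are tested: the row sums of the Poisson operator vanish exactly
over the fluid region (its left null-vector is the constant), and the sum of
discrete boundary fluxes equals the imposed net flux to rounding error. The
pressure nullspace is pinned and reported pressures are shifted to zero
volume-weighted mean each step; every reported measure is a pressure
*difference*, so the choice is immaterial (and tested as such).

All implicit operators and the Poisson matrix are LU-factorized once per run
and reused at every step, which is what makes 10⁴-step runs on ~10³–10⁴-cell
grids take seconds to minutes in plain R.

**Boundary conditions.** Dirichlet velocity on the entire boundary: no-slip
at walls, and on open boundaries the instantaneous flux distributed by the
wall-distance weight τ(x) (a tent profile, zero exactly at wall junctions;
a parabolic option exists). The discrete normalization uses the same face
quadrature as the solver's flux operator, so the imposed discrete flux equals
Q(t) exactly. Outflow boundaries use the same profile with the waveform's
sign. Unassigned open boundaries receive the mass-balance remainder
(`mass_balance_split()`), divided across inlets proportionally to area.
Verification runs may instead drive a boundary with an exact closed-form
profile (`boundary_profile()`), e.g. the oscillatory channel solution.

**Time step and run length.** Runs start from zero velocity and cover 3
cardiac cycles (the flow is periodic from the second cycle; the per-series
periodicity residual between the final two cycles is reported, with 1 % as
the logged warning threshold). The reference setting (`mode = "paper"`) uses
Δt = 10⁻⁴ s. Test mode uses Δt = 4·10⁻⁴ s: at the stenosed preset's peak
throat velocity (~0.12 m/s) the explicit-convection growth must stay below
the viscous damping at every wavenumber, and 4·10⁻⁴ s keeps a comfortable
margin where 5·10⁻⁴ s would be thin. The step actually used divides the
period exactly so that cycles align sample-for-sample.

## Hydrodynamic measures

With stations CS (cervical), PC (pontine cistern) and Aq (aqueduct):
Δp_PC−CS = p_PC − p_CS and Δp_Aq−PC = p_Aq − p_PC, pointwise on the shared
final-cycle grid — each drop is upstream minus downstream, and the two
telescope to p_Aq − p_CS (a tested identity). On units:

* Resistances R_sys = Δp_max/|Q_sys| and R_dia = |Δp_min|/Q_dia are reported
  in g/(mm⁴·s). The unit conversion is fixed by dimensional analysis —
  1 Pa = 1 g/(mm·s²), so Pa per (mm³/s) *is* g/(mm⁴·s) with factor one — and
  is unit-tested against a hand-computed case.

The phase difference is θ = (t_umax − t_Δpmax)/T with t_umax the time of peak
systolic slice velocity at CS, t_Δpmax the time of the Δp_PC−CS maximum, and
T the **caudal-flow duration** (normalizing by the full cycle period is a
plausible alternative convention; comparisons across sources need care on
this point). On sign: momentum balance along the duct gives
Δp_PC−CS = −(ρL/A)·dQ/dt for inertia-dominated flow — the pressure above must
exceed the pressure below while caudal flow accelerates — so the drop peaks
at flow reversal and the pure-inertia limit is θ = +1/2, with viscosity
pulling θ below that. The oscillatory-channel test pins this sign against the
closed form.

The foramen-magnum region for regional peak velocities is defined
geometrically (stenosis throat ± one nominal gap width): the idealized
geometry has no anatomical landmark. The bidirectional-flow fraction counts
final-cycle snapshots in which a transect carries both flow directions above
a noise floor of 1 % of the slice's cycle-peak speed. Report tables round
velocities to whole mm/s, pressures to 0.1 Pa and resistances to 3 decimals;
across-subject ratio tables compare magnitudes and are printed to one
decimal.

## Mesh-independence metrics

Two metrics compare a run against a ~2×-refined rerun (cell-count ratio ≈ 2,
i.e. √2 per direction, mirroring the coarse-to-fine mesh doubling convention):

* **e_Δp**: the signed percentage difference of the cycle-maximum Δp_PC−CS.
* **e_|u|**: the maximum percentage difference of |u| along fixed transects
  (defaults: mid-stenosis and mid-cervical), the fine field interpolated to
  the coarse positions — i.e. the pointwise relative difference of |u|,
  maximized along the line. Points where the fine |u| falls below 1 % of the
  transect peak are excluded (relative differences blow up where the
  velocity is small near walls), as are vortex regions, detected as sign
  changes of the axial velocity along the line.

Both metrics are scale-invariant (tested). The shipped stenosed-annulus pair
(0.15 mm transverse cells, 3200 → 6328 cells) satisfies e_Δp < 1 % and
e_|u| ≤ 10 % outside exclusions; the resolution was selected so the pair has
this property, which is asserted by the acceptance tests rather than claimed
here.

## Numerical choices and degenerate inputs

* Linear solves are direct (sparse LU); post-projection divergence is at
  rounding level, far below the nominal 10⁻⁸ 1/s tolerance the invariant
  checks use.
* Waveform readers require ≥ 8 strictly increasing samples and finite fluxes;
  the heart rate comes from a `# heart_rate_bpm` header when present (making
  write/read round trips bit-exact) and is otherwise inferred from the sample
  span, which is approximate by up to one sample spacing.
* A constant-sign waveform has no flow reversal: origin alignment fails with
  an explicit error. A zero waveform yields identically zero fields (tested).
* Geometry presets reject occlusions ≥ 1 and transverse cells larger than
  half the narrowest gap ("stenosis unresolved").
* In the Stokes limit (`convection = FALSE`) the scheme is exactly linear in
  the driving flux; doubling Q doubles u and p to rounding error (tested),
  and resistances are amplitude-independent.

## Problem sizes

The shipped configurations are deliberately desk-scale: the verification
channel uses 32 cells across the gap, the stenosed annulus 20 × 160 cells
(coarse) and ~2× that (fine), the branched domain ~700 fluid cells, all at
Δt = 4·10⁻⁴ s for 3 cycles. These sizes make every simulation in the test
suite and acceptance script run in seconds to a couple of minutes on a single
CPU while keeping all verification bounds comfortably met; refining further
is a preset parameter away (`make_geometry(preset, refine = )`).

## Limitations

* Rigid walls and strict mass conservation: no craniospinal compliance, no
  along-canal flow amplitude change from tissue motion.
* 2-D planar/axisymmetric idealizations: no patient anatomy, no 3-D jet
  instability or transitional flow; the high-Reynolds features a severe
  stenosis can develop in 3-D are out of scope.
* Laminar Newtonian flow only; no microstructures (trabeculae, nerve roots,
  denticulate ligaments), which are known to alter local pressures.
* Resistance is the simple peak-ratio definition; longitudinal impedance,
  which accounts for tapering and pulsatility, is not implemented.
* Patient-specific absolute velocities and pressures are not reproducible
  from this package by construction — they require patient meshes and raw
  PC-MRI data. The acceptance checks therefore verify the *method*: analytic
  oracles, conservation structure, convergence orders, periodicity and the
  mesh-independence bounds, plus the worked examples that follow from the
  bundled reference summary table.
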