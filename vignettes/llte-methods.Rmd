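---
title: "Methods: the lower leg trajectory error design framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lower leg trajectory error design framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lltefoot)
```

This vignette records the modelling assumptions, numerical choices and
known limitations behind `lltefoot`. It is the reference for *why* the
package computes what it computes; the README shows *how* to run it.

## The design problem

A passive energy-storage-and-return (ESR) prosthetic foot is a compliant
2-D structure clamped to the shank through a rigid adapter. Under the
loads of walking it deforms, and the deformation — together with the
ground-contact constraints — determines where the user's knee travels
through stance. The lower leg trajectory error (LLTE) is the root of the
mean, over a set of stance instances, of squared deviations between the
model-predicted knee position and shank angle and an able-bodied
reference trajectory, each deviation normalized by the mean absolute
value of its reference variable over the portion of the step considered.
Minimizing the LLTE over a parametric foot family gives a user-specific
design.

Two modelling assumptions carry the whole framework:

* **Quasi-static structure.** Foot inertia and damping are neglected;
  each stance instance is an independent equilibrium problem under the
  instantaneous ground reaction force (GRF) applied at the instantaneous
  centre of pressure (CoP).
* **Rigid lower leg.** Shank and socket are rigid and rigidly attached to
  the foot at the ankle block; the "knee" is a virtual point that sits on
  the vertical through the ankle, one lower-leg length above the ground,
  when the foot is flat and unloaded (the calibration pose).

## Frames, signs, conventions

| Quantity | Convention |
|---|---|
| lab frame | x forward (walking direction), y up; origin on the ground below the ankle at calibration |
| foot frame | origin at the C1 (ankle) circle centre; unloaded sole rests on y = −h_ank |
| `cop_x` (gait tables) | heel-relative; the ankle sits at 25% of foot length from the heel (configurable `ankle_fraction`) |
| `cop_x` (load cases) | lab/ankle frame (shifted by −0.25 · L_foot) |
| `theta_shank` | degrees, positive with the knee anterior to the ankle |
| foot orientation `phi` | degrees, positive in the dorsiflexion direction; equals `theta_shank` for the rigidly attached shank |
| knee moment | N·m, positive counterclockwise with +x forward |

Angles are degrees at every interface and radians internally.

## The synthetic reference gait

The published able-bodied dataset the framework was built around is not
redistributable, so the package ships a generator
(`synthesize_reference_gait()`) whose defaults emulate level-ground
walking at a self-selected speed for a 70 kg subject with a 0.26 m foot
and 0.50 m lower leg:

* vertical GRF: two Gaussian peaks (1.15 and 1.12 body weight at 25% and
  76% of stance, width 0.14) under a smooth contact envelope, giving
  exactly two local maxima in (0.9, 1.3) BW;
* fore-aft GRF: braking then propulsion, ±0.17 BW;
* CoP: monotone smoothstep from the heel to 83% of foot length;
* shank angle: an inverted-pendulum progression,
  `theta = asin(cop_ankle / L_leg)` through mid-stance, blended into a
  −15° heel-strike attitude and a +25° push-off attitude by Gaussian
  transients (widths 0.15 and 0.18 of stance). This keeps the knee
  roughly over the CoP through mid-stance so the implied knee moments
  stay small and physiological (|M| < ~50 N·m); an earlier symmetric
  profile that crossed zero at 50% of stance implied ~60 N·m mid-stance
  knee moments and was discarded as unrealistic;
* knee point: `L_leg` along the shank from the ankle ground point;
* knee moment: computed from the cross product `(CoP − knee) × GRF` at
  every frame, so the moment-consistency identity holds exactly by
  construction;
* a small seeded low-order Fourier perturbation (1% scale) makes seeds
  distinct while preserving every container invariant.

What the generator does **not** emulate: trial-to-trial variability,
double support coupling between legs (each stance is generated alone),
3-D effects, soft-tissue artefacts. Tests that pass against this
generator therefore validate the *computations*, not the framework's
clinical performance on real gait.

Scaling to a user multiplies GRFs by the mass ratio, CoP by the
foot-length ratio and knee coordinates by the leg-length ratio; knee
moments scale with mass ratio × leg-length ratio (force × lever). When
foot and leg ratios differ, the flat-contact moment identity is preserved
only approximately — exact preservation would require re-deriving the
moment from the scaled kinetics, which would silently change the
reference data, so the simple multiplicative rule was kept.

## Foot parametrization and meshing

Six control circles define three wide Bézier curves (cubic keel C1→C4,
linear forefoot C4→C5 and heel C4→C6). The centreline is the Bézier of
the centres; the half-thickness is the same-degree Bernstein
interpolation of the radii, and the boundary is the centreline offset
along the local normal. All three segments end at C4 with the C4 radius
(Bernstein endpoint property), which makes the junction blend exact.
Dependent values: C1 at the origin; C5/C6 abscissae at ±(1, −1) ×
(0.75, 0.25) · L_foot; C4, C5, C6 centres at `−h_ank + d/2` (resting on
the ground line). Out-of-plane width is a plain extrusion depth, default
0.060 m — it enters area and second moment only.

Self-intersection is checked by brute-force segment crossing between the
six offset polylines, excluding crossings within ~1.2 × (r4 + local
half-thicknesses) of C4 where the three thick segments legitimately
merge. Meshing allocates elements to segments by arc length (default
300 elements; the cantilever-style tip response of the shipped example
foot changes by <1% between 300 and 600 elements), with thickness per
element the mean of its endpoint thicknesses.

## Structural solver

2-node plane-frame elements (axial + Euler–Bernoulli bending, 3 DOF per
node), corotational kinematics, incremental load application (default 10
increments) with Newton iterations per increment to a relative force
residual of 1e-6 (50 iterations maximum). A displacement-increment
criterion (`|du| ≤ tol·|u|`) accepts convergence when the force residual
floors at the cancellation noise of very stiff structures — this is what
makes near-rigid limit checks possible. Shear deformation, self-weight
and inertia are neglected (slender elements, quasi-static loading).

Bending stiffness and bending stress use the flexural modulus and yield
(E_f, σ_yf), axial terms the tensile pair (E, σ_y); both are
configurable in `solver_options()` because the original usage is not
uniquely determined. The safety check compares the combined
extreme-fibre stress `|N/A| + |M c / I|` against σ_yf / 1.75.

## Contact kinematics

**Flat contact (mid-stance).** The GRF (rotated into the foot frame) is
applied at the sole node nearest the CoP station (point-load
idealization, no smoothing). The foot orientation is fixed-point
iterated (`phi ← −local sole slope`) until the deformed bottom fibre is
ground-parallel at the loaded node, tolerance 1e-4 rad. The deformed
contact point is then placed at `(cop_x, 0)` and the knee follows
rigidly. Consequence worth stating explicitly: a *rigid flat-soled* foot
keeps its lower leg stationary as the CoP advances — rolling a flat sole
without slip moves nothing. The compliant keel is what lets the shank
progress; this is precisely the property the LLTE optimization exploits.

**Line contact (heel strike / toe off).** The CoP pins the pivot sole
node to the ground, and the orientation is the root of
`M(phi) − M_ref`, where `M(phi)` is the knee moment implied by the pose.
The bracket is grown outward from the warm start (2° steps, doubling, up
to ±45°) until the residual changes sign, then polished by `uniroot`;
the returned residual is below 0.1 N·m. The warm start is the previous
instance's orientation (reference shank angle for the first), which
selects the physical branch when several roots exist.

Failed instances (non-convergence, no bracket) are flagged, and each
contributes a squared penalty of 10² to the LLTE so any feasible design
outranks an infeasible one.

## Optimization

Real-coded GA on the 11 bound-scaled variables: tournament of 3, blend
(BLX-0.5) crossover at 0.9, per-gene Gaussian mutation (sd 0.1) at 0.15,
population 50, 60 generations, one elite, fixed seed. Constraints are
static penalties: out-of-bounds and self-intersection short-circuit
(no structural analysis) to 1e3 plus a violation magnitude; a stress
violation adds `10 × (max_stress/allowable − 1)`. Feasibility of the
returned design is re-checked outside the penalty path in the tests.

## The two-variable analytic foot

Design studies that need thousands of evaluations (instance-set
sufficiency, optimizer verification against exhaustive grids) use
`analytic_foot()`: a rigid flat sole whose keel and heel act as
cantilever arms of lumped stiffness `EI = E_f w t³/12`, with the two
thickness scales as the free variables. Flat-contact pose in closed form
(sole slope `F_y d²/(2EI)` at lever arm d), line contact by rigid pivot
with arm-tip bending. The instance-set study (`instance_set_study()`)
grids both scales 50 × 50 over [0.5, 1.5] and compares the optimum under
the nine representative instances with the optimum under all of 1–99%.
Under the shipped synthetic reference this family has an irreducible
misfit to the reference shank progression (its slope grows with the
square of the lever arm, the reference's roughly linearly), so the two
instance sets weight that misfit differently and the keel-scale optima
can sit ~15–20% apart even though the *LLTE of the fixed optimum* agrees
within a few percent across the sets. With richer families (the
11-variable wide Bézier foot) the optimum is pinned by many more active
constraints per instance.

## Gait-analysis layer

* **Filtering**: 4th-order zero-phase Butterworth, 6 Hz kinematic /
  12 Hz kinetic. The implementation removes the endpoint-to-endpoint
  linear trend and pads by odd reflection before the forward–backward
  pass, because raw `filtfilt` leaks edge transients several hundred
  milliseconds into short recordings. CoP is not filtered: it is a
  derived location, undefined when unloaded, and filtering across the
  between-step discontinuity would smear the jump into early stance.
* **Stance detection**: vertical GRF ≥ 40 N, with sub-10 ms gaps and
  islands merged away.
* **Roll-over shape**: CoP from heel strike to opposite heel strike,
  transformed into the shank-fixed frame and fitted by a least-squares
  circle. Only samples with vertical load ≥ 10% body weight enter the
  fit (force-plate CoP is unreliable at low loads, and the 6 Hz marker
  filter leaks swing accelerations into the first/last ~50 ms of
  stance); the radius is reported normalized by lower leg length.
* **Foot power**: unified-deformable distal shank power
  `P = F·v + M_free·ω`, with v the velocity of the shank material point
  instantaneously at the CoP. "Energy returned" is integrated from the
  final negative-to-positive power crossing to toe off — a plain
  stance-long integral would give net work, near zero for an elastic
  foot, which does not match the physical meaning of stored-and-returned
  energy; the net work is also reported.
* **CoM transition work**: per-limb external power `F_limb · v_CoM`,
  with `v_CoM` integrated from the summed GRFs under periodicity
  constraints (velocity periodic over the stride, mean forward velocity
  equal to the walking speed, zero mean vertical velocity). Collision is
  the negative-power integral of the leading limb over double support,
  propulsion the positive-power integral of the trailing limb; the
  leading limb is the one that landed last, with intervals truncated at
  the recording start not counted as contacts.
* **Deviation scores**: per-variable NRMSE with normalizers body weight
  (GRFs), foot length (CoP), lower leg length (knee coordinates) and the
  reference shank-angle range (angle); total = sum over both legs.

## The synthetic step recording

`synthesize_step_recording()` builds one stride of markers (120 Hz) and
per-side force plates (960 Hz) from closed-form components with known
ground truth: exact rigid-rocker rolling for the stance-leg kinematics
(so the roll-over shape is a circle of the programmed radius and the
rigid contact-point velocity vanishes identically), periodic double-peak
GRFs rescaled so the stride average supports body weight exactly, trunk
roll for the sway range, ±half step width ankle offsets, and Gaussian
bump programs for the foot-shank angle peaks. The programmed elastic
energy enters through the free-moment channel, constructed so
`M_free·ω` integrates to the requested stored/returned work — a
synthetic truth-injection device, not a claim that real free moments
look like this; with it set to zero the recording is a rigid roller and
the distal power is numerically zero. Swing trajectories are smooth
blends with velocity-matched contacts (zero-slope lifts, transient-free
envelopes) so filtering artefacts at the transitions stay small. A 0.15 s
lead-in keeps filter edge effects clear of the first stance. Gaussian
measurement noise (0.1 mm markers, 2 N forces) is seeded and optional.

Problem sizes used throughout the tests were chosen to exercise the
numerics at meaningful resolution while keeping a full run lightweight:
30–60 frame elements and 4–5 load increments in optimization loops
(300/10 are the production defaults), 20-seed recording sweeps, 50 × 50
design grids.

## Known limitations

* Sagittal plane only; no out-of-plane stiffness, torsion, or frontal
  contact geometry.
* Point-load contact at a single sole node; no distributed pressure and
  no load smoothing, so poses are resolved only up to the mesh's sole
  node spacing.
* No material damping, plasticity or fatigue; the stress constraint is a
  static allowable with a fixed safety factor.
* The reference gait and step recordings are synthetic; absolute LLTE
  magnitudes depend on the generator's curve shapes and are not
  comparable across different reference datasets.
* Knee-moment scaling under user scaling is exact only when foot-length
  and leg-length ratios coincide.
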