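---
title: "Muscle-effort-minimal precision grips: model, assumptions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle-effort-minimal precision grips: model, assumptions and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gripsynth predicts how a human hand pinches an object: which fingertip
positions, hand posture, fingertip forces and muscle activations hold the
object stably while minimizing the summed squared muscle activation. This
vignette explains the model layer by layer, the parameters that matter,
the numerical choices, and what the packaged test scenario does and does
not demonstrate.

## The musculoskeletal hand

The hand is a chain of 21 rigid bone segments: forearm, carpus (the carpal
bones fused into one body), five metacarpals and fourteen phalanges. Joints
are revolute: the thumb carpometacarpal and metacarpophalangeal joints and
all finger metacarpophalangeal joints carry two axes (flexion–extension and
adduction–abduction), the interphalangeal joints one; carpometacarpal
joints 2–5 are immobile. That yields exactly 21 actuated axes — one per
column of the muscle moment-arm table, so every tabulated arm maps to an
actuated axis and none is orphaned. Two-axis joints compose
flexion–extension first, then adduction–abduction about the flexed frame;
this intrinsic order is a convention, stated so results are reproducible.

Subject-specific bone geometry from imaging is not portable, so the
segment lengths, metacarpal bases and joint axes are parametric, with
packaged defaults from generic adult-hand anthropometry (~19 cm hand) that
scale jointly through `hand_scale`. The palmar surface is approximated by
65 spheres attached to the segments; they serve the non-penetration
penalty and the fingertip contact sites (below). Because moment arms are
constant and the geometry generic, absolute effort values are
model-dependent; comparisons *within* the model (between candidate grips)
are the meaningful output.

Thirty-seven muscles act on the 21 axes through constant, signed moment
arms (mm; positive = flexion/adduction). No pennation angle and no
force–length or force–velocity scaling are modelled. The parameter table
ships verbatim as `muscles.csv`. Two transcription notes: the
middle-finger deep flexor is stored under the unique abbreviation FDP3,
and the index deep flexor's proximal-interphalangeal arm keeps its
tabulated, anomalously extensor-signed value of −8.5 mm.

### Muscle strength units

The tabulated "maximum forces" are a few newtons per muscle (65.1 N for
the whole hand). Taken literally they cannot hold even a 200 g object: at
any pinch-like posture the required activations exceed the printed maxima
by a factor of 20–40 (measured by bisecting the smallest feasible
activation bound of the grasp program). The magnitudes instead match
relative tension capacities proportional to physiological cross-sectional
area, the classical way hand-muscle strength is tabulated, and maximum
force is conventionally PCSA times a specific tension of 35 N/cm².
`load_muscle_table(strength_scale =)` makes the conversion explicit: the
default 1 keeps the printed values (so unit tests against the table read
literally), while the synthesis pipeline defaults to
`strength_scale = 100` N per printed unit. The value 100 rather than 35
is a deliberate design choice for the *parametric* hand: off-centre grips
must resist gravitational torsion through friction at 2 mm-separated
contact pairs, which multiplies grip-force demand several-fold (measured
grip forces in comparable experiments triple or quadruple off-centre),
and the generic chain lacks the geometric advantages of a real hand —
broad pulp contact patches, posture-dependent moment arms, passive
tissue. The extra headroom restores the protocol range the model is
meant to execute. Effort is a function of activations only, so the scale
affects feasibility and magnitude, not the ordering of candidate grips.

## Grasp mechanics

Object equilibrium is `G f = [-m g; 0]` with the 6 × 3n grasp matrix
stacking identity blocks over skew blocks `S(r_k)`, `r_k` from the centre
of mass to contact k, and gravity fixed at (0, 0, −9.81) m/s². Coulomb
friction cones (apex angle `atan(μ)`) are linearized as twelve-sided
pyramids *inscribed* in the cone: the pyramid's edge rays lie on the exact
cone, so pyramid-admissible forces are always cone-admissible and the
no-slip guarantee is conservative (forces with tangential/normal ratio up
to `μ cos(π/12)` are always admitted). The strict inequality of the cone
condition is implemented as ≤ 0 — a closed feasible set as quadratic
programming requires — and the inward normal ray is strictly interior, so
this loses nothing. Facet normals are built by rotating the contact
tangent basis through twelve equal azimuths, which is what the edge-ray
tests reproduce independently.

A fingertip pad transmits torsion about the contact normal. Following the
device-validation convention, each grasping distal phalanx contributes a
*pair* of contact points 2 mm either side of the contact centroid, split
along the phalanx's medio-lateral axis projected into the plate (falling
back to the plate's long axis if degenerate). Equal and opposite
tangential forces at the pair form a couple with a 4 mm arm.

## The effort program

Over `x = [f; a]`, minimize `E = Σ a_i²` subject to equilibrium, the force
balance `J^T f = M^T F^max a` over the 21 actuated axes (the six
carpal-base freedoms are unactuated and excluded), friction facets
`N f ≤ 0` and bounds `0 ≤ a ≤ 1`. This is convex but has no curvature in
`f`; a ridge of `1e-7` on the force block makes it strictly convex and
selects the minimum-norm force distribution among effort-optimal ones —
one deterministic solve in place of a lexicographic second stage, with an
effort perturbation bounded by `1e-7‖f‖²` (≈ 1e-5 for the largest grips
handled here). Both backends substitute `x = D^(-1/2) y` so the objective
becomes the identity and all conditioning moves into the constraints,
where the dual active-set method's QR factorization absorbs it: the
`"activeset"` backend solves the full stacked form, the `"nullspace"`
backend first eliminates the equalities through an orthonormal SVD basis
(tolerating the rank deficiency soft-contact pairs can induce) and solves
an inequality-only program. The two routes agree to 1e-6 on every tested
problem and a multi-start barrier solver reproduces the optimum to 1e-5
on small randomized instances.

When no activation pattern satisfies the constraints at a posture, the
posture is scored `100 + Σ (q_j − q0_j)²`. Any constant above the largest
possible effort (37, all muscles saturated) preserves the ordering
"feasible beats infeasible"; 100 is used, and the deviation term ranks
infeasible postures by naturalness so the outer search still receives a
gradient toward plausible hands.

## Inverse kinematics

For target fingertip positions the carpal pose and joint angles minimize

L = w1 Σ |d_l − d_l⁰|² + w2 Σ s_m² + w3 |p − p⁰|² + w4 |e − e⁰|² + w5 |q − q⁰|²

by L-BFGS-B with box limits on the joint angles. Choices worth stating:

* **Penetration term.** `s_m` is read as the penetration *depth* of skin
  sphere m (squared once in L). The alternative reading (depth² summed as
  depth⁴) is so flat near the surface that it provides no useful
  restoring gradient; depth² behaves like a stiff unilateral spring.
* **Contact sites are spheres, not bone points.** The "tip" site is the
  terminal skin sphere of the distal phalanx, the "pulp" site the mid-pad
  sphere. Targets place the sphere *centre* one radius off the surface
  (minus a 1.5 mm `press_depth` emulating pad compression), so tangency is
  independent of phalanx orientation. Targeting a bone apex instead
  couples orientation to penetration and stalls the optimizer several
  millimetres short.
* **Weights** (unpublished in the source method) default to w1 = w2 = 100,
  w3 = w4 = 1, w5 = 0.1 in SI units: contact and non-penetration dominate;
  posture naturalness regularizes. All configurable.
* **Gradients** are analytic — identity in carpal translation, the SO(3)
  right-Jacobian pullback for the rotation vector, `axis × (point − centre)`
  per joint — and validated against central differences to 1e-6 in the
  test suite. Orientation is carried as a rotation vector; convergence is
  L-BFGS-B's relative-reduction rule with a 500-iteration default cap.
* Only fingers that grasp contribute the target term; uninvolved fingers
  stay pinned at the natural posture (curled into the palm, clear of the
  object).

The natural posture `q0` deserves a note: it holds the thumb opposed and
the index moderately flexed so that, near contact, the distal segments
meet the plates nearly bone-on. Fingertip forces are then transmitted
axially through the phalanges — force lines passing close to the joint
axes — which is both how real pinches work and what keeps torque demands
within muscle capacity.

## Outer search

CMA-ES (standard rank-one plus rank-mu covariance adaptation with
cumulative step-size control, implemented in-package) searches the
in-plane (u, v) coordinates of each grasping fingertip on its assigned
surface — four variables for a thumb–index pinch. Population is the usual
`4 + ⌊3 ln d⌋`; the initial step size defaults to the *largest* patch
half-extent (24.5 mm on the packaged device). A smaller step (e.g. half
the short plate dimension) empirically strands far-end starts on the
infeasibility plateau; sampling the entire surface in the first
generations is required for the far-end and near-end starts to converge
to the same optimum, which they do here to ~0.1% in effort. Out-of-bounds
samples are reflected back into the box (triangle-wave reflection), never
clipped, so the sampling distribution stays consistent. Runs are exactly
reproducible for a fixed seed. Each candidate warm-starts its inverse
kinematics from the incumbent best posture.

## The packaged scenario, and what it does not show

The shipped fixture is the two-plate force-sensing device: 198.4 g, two
20 × 49 mm plates 40 mm apart (separation and friction are configurable;
defaults 40 mm and μ = 0.8, planned as 0.4). The long plate axis is
horizontal: only horizontal offsets from the centre of mass generate
gravitational torsion about the plate normal, which is the mechanism that
makes off-centre pinches costly and centre pinches optimal. On this
fixture the package reproduces the expected qualitative physics:

* effort is minimal at the plate centre and rises steeply toward either
  end (within ±3 mm it roughly triples);
* pulp grips cost less than fingertip grips at matched positions;
* searches started at opposite plate ends agree in final effort within a
  few tenths of a percent;
* the vertical components of the solved contact forces recover the object
  mass exactly, by construction of the equilibrium constraint — the
  acceptance script recomputes this end to end.

Deliberate simplifications: the object pose is *fixed upright*. A human
pinching the far end of such a device lets it tilt so the centre of mass
hangs under the grip axis, converting most of the torsion into in-plane
force; with the pose fixed, far-end grips are genuinely near-infeasible
and the packaged sweeps therefore use modest (±3 mm) offsets. Object
orientation as a search variable is the natural extension. Further
limitations inherited from the model class: constant moment arms, no
muscle dynamics or passive joint elasticity, a box signed distance (plates
flush with the housing), and a generic rather than subject-specific hand,
so absolute effort values and activation patterns indicate tendencies,
not subject predictions.

## Problem sizes in the tests

The test suite runs the full pinch pipeline at reduced budgets chosen for
quick iteration: inner IK capped at 100–150 iterations, searches at
20–30 generations with population 8 (the effort landscape on the plates
is smooth enough that both far-end starts settle by then), friction-cone
sampling at 10⁴ random forces, QP oracles on two-contact problems with
four to six muscles, and the grid oracle at 10⁻³ resolution with a 10⁻⁶
refinement pass around the optimum. The acceptance script synthesizes one
seeded grasp (20 generations) and reports the recovered object mass.
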