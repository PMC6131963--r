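---
title: "Structural mechanics of the tree-frog digital pad: models, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural mechanics of the tree-frog digital pad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(padmech)
```

## The scientific question

Tree frogs attach to vertical substrates mostly through friction: shear
loads taken up by the ventral surface of the digital pads must travel
through the dermal tissue to the skeleton. The ventral collagen layer — a
longitudinally fibred sheet pierced by mucus ducts and organised into
lateral ridges — is the prime candidate for this load path. `padmech`
implements the numerical side of that argument as a reproducible pipeline:

1. a parametric, voxelised model of the collagen layer (`pad_geometry`);
2. a linear-elastic finite-element solver on that voxel mesh (`voxel_fem`);
3. stiffness-maximising topology optimisation under the physiological
   shear load (`topopt`) — does an optimal material layout *recreate* the
   observed morphology (ridges, distal flattening, curved fibre paths)?
4. stress post-processing: von Mises contrasts, principal-stress
   trajectories, ridge profiles (`stress_analysis`);
5. analytic tensile load budgets of the force-transmitting structures
   (`strength_budget`);
6. peeling mechanics: the Kendall thin-film model and a contact-stress
   comparison of septum loading versus proximal pulling (`peel_models`).

The repository is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the package functions
and write their tables and fields under `results/`.

## The pad model

The collagen layer is idealised as a 1.5 x 1.0 x 0.45 mm box (proximal at
x = 0, ventral at z = 0, mid-sagittal plane at y = 0.5 mm; mm–N–MPa
units). Three longitudinal rows of five vertical holes (diameter 0.1 mm)
represent the mucus ducts. Two printed spacings are interpreted as
centre-to-centre distances: 0.14 mm within a row and 0.25 mm between
rows. Edge-to-edge spacing would spread five holes over more than a
millimetre and crowd the pad implausibly; centre-to-centre leaves 0.04 mm
webs between holes, matching the rendered geometry. The hole field is
centred in the middle third of the pad length (configurable offset), and
a quarter-cylinder scoop of radius 0.3 x height at the dorsoproximal edge
stands in for the proximal epiphysis of the distal phalanx; its true
shape is not published, so shape and radius are configuration parameters.

Voxelisation uses a centre-membership rule: a voxel is void exactly when
its centre falls inside a hole cylinder or the recess. There are no
partial volumes; instead the tests verify that the voxelised duct volume
approaches the analytic cylinder volume (about 7.85% of the box) as the
grid is refined. The lattice error oscillates at coarse grids — a
consequence of counting lattice points in discs — so convergence is
asserted at the finest tested doubling (120x80x36 to 240x160x72, where
the error drops more than tenfold).

The morphometry table bundled with the package
(`morphometry_fixture()`, exported to `inst/extdata/morphometry_synthetic.csv`)
emulates the published cross-sectional measurements of the three
force-transmitting structures: collagen layer 20,000–65,000 um^2 and
septum 6,500–7,500 um^2 (both at an assumed 100 MPa tensile strength of
dense collagen), muscle bundles 7,000–14,000 um^2 at 0.2–0.4 MPa. It is a
synthetic stand-in for the original per-digit measurements, which are not
published as a table; only the printed ranges are represented.

## Elasticity on the voxel mesh

Each voxel is an 8-node trilinear hexahedron with full 2x2x2 Gauss
integration; material is isotropic with E = 20 MPa and nu = 0.33, a
published mid-range for collagenous tissue. Element stiffness follows the
SIMP interpolation `E(rho) = E0 (1e-9 + rho^p (1 - 1e-9))` with p = 3; the
1e-9 floor keeps emptied voxels from making the system singular. The load
case is the physiological one: the ventral face fully fixed (the adhered,
non-removable contact surface) and a 3.815 mN tensile pull on the solid
part of the proximal face — the body weight of a 7 g frog spread over 18
digits, applied as a uniform traction (equal shares per solid voxel face,
quarter shares to face nodes, which is the consistent nodal load of a
uniform traction on trilinear elements).

Two linear solvers honour the same contract (relative residual at most
1e-8): sparse Cholesky factorisation for systems up to ~25k free DOFs,
and Jacobi-preconditioned conjugate gradients with warm starts above
that. The choice is automatic and can be overridden. Correctness rests
on four independent checks: the constant-stress patch test is exact for
trilinear elements; solutions on domains up to 3x3x3 voxels match a dense
brute-force solve to 1e-10; reactions balance applied loads to 1e-6
relative on every solved case; and the tip displacement of a slender
cantilever changes by under 2% between 24x6x6 and 48x12x12 meshes.

Element-centroid stresses come from the strain–displacement operator and
Hooke's law with the same SIMP modulus. Tension is positive; the
"maximum principal stress" is the algebraically largest eigenvalue, and
its eigenvector field underlies the trajectory tracing.

## Topology optimisation

The optimiser minimises compliance `C = u'f` (maximises stiffness) under
a stepped volume schedule copied from the study design: 60% of the
initial solid volume removed in 24 steps of 2.5%. Each stage applies
optimality-criteria updates (move limit 0.2, damping exponent 0.5,
Lagrange-multiplier bisection) after smoothing sensitivities with a
linear-decay mesh-independency filter of radius 1.5 voxel edges. The
original study used a proprietary optimiser whose internals are
unpublished; SIMP with optimality criteria is the standard open method
with the same objective and constraint, so agreement is expected — and
asserted — only at the level of the qualitative outcome.

Three structural constraints shape the design space: hole and recess
voxels are hard void; the ventral voxel layer is frozen at full density
(the contact surface may not be removed); and the density field is kept
exactly mirror-symmetric about the mid-sagittal plane by averaging with
its mirror image after every update.

The state problem exploits that same symmetry: the elastic solve runs on
the lateral half domain with `uy = 0` on the mirror plane and is expanded
back (the tests verify this against the full solve to solver precision),
halving the dominant cost.

Two numerical conventions deserve a note:

* **Stage convergence.** A stage ends when the maximum per-voxel density
  change drops below 0.01 or after `inner_iters_max` iterations. Under a
  move limit of 0.2 the emptying regions drift at the limit for many
  iterations, so the max-norm criterion essentially never fires early;
  stages end at the cap with a warning, which is the intended
  "proceed with the best iterate" behaviour. The qualitative optimised
  morphology is insensitive to the cap: runs with 4, 6, and 30
  iterations per stage produce the same troughs, ridges, and distal
  flattening. The analysis scripts use 6 iterations per stage at
  30x20x9 and the acceptance script 4 per stage at 60x40x18; the
  schedule itself (24 stages of 2.5%) is never altered, and every stage
  hits its volume target to 1e-4 by bisection regardless of the cap.
* **Compliance bookkeeping.** The per-stage compliance is the one
  computed by the last state solve within the stage (densities already at
  the stage's volume target); the final density field is re-solved once
  more for the reported end-state compliance. Recorded compliance is
  non-decreasing across stages, as it must be when the volume constraint
  tightens.

Problem sizes: the test suite and analysis scripts run the full 24-stage
schedule at 30x20x9 voxels (0.05 mm edges, ~5,400 elements); the
acceptance script runs it at 60x40x18 (0.025 mm edges, 43,200 elements).
Both are far coarser than the ~250,000-element mesh of the original
study, which is why only sign- and trend-level reproduction is claimed
for the field patterns.

## Stress trajectories and contrasts

Force-transmission paths are streamlines of the unit eigenvector field of
the largest principal stress: fixed-step RK4 (half a voxel edge) on
tensors interpolated trilinearly between element centroids and
eigen-decomposed at each sample. Eigenvectors carry an inherent sign
ambiguity; the integrator resolves it by sign continuity, flipping any
eigenvector that reverses against the previous direction, and the tests
drive a deliberately rotating field through the tracer to confirm no
reversal jumps occur. Trajectories terminate on leaving the box, entering
void or sub-threshold material (rho < 0.5), or after a step budget.
Seeds default to a 5x5 grid on the loaded proximal face; seeds falling in
the recess are skipped with a warning.

The von Mises contrast report classifies solid voxels of the duct band
(the longitudinal interval spanned by the hole field): intra-row webs lie
within half a hole pitch of a row ordinate, longitudinally between the
outermost holes of the row; inter-row webs lie strictly between adjacent
row ordinates, more than half a pitch from either. The report returns the
two means, their ratio, and mean von Mises per longitudinal quartile.

## Strength budgets

Capacities are plain `area x strength` bounds with the unit identity
1 um^2 x 1 MPa = 1e-6 N: 2.0–6.5 N for the collagen layer, 0.65–0.75 N
for the septum, and single millinewtons for the muscle bundles. The
report's `capacity_N_min`/`capacity_N_max` pair the smallest area with
the lowest strength and the largest with the highest; note that the
published 2.8–5.6 mN muscle range instead holds the area at its maximum
while sweeping the strength, so its lower end corresponds to
`tensile_capacity(14000, 0.2)`. Because the septum and the dorsoventral
muscle bundles jointly carry normal loads, their summed capacity is
reported as an extra row. No stress-concentration or fatigue corrections
are applied — the estimate is deliberately a first-order bound, and the
caveat that area and strength may be overestimated for loose collagen
applies here unchanged.

## Peeling mechanics

`kendall_peel_force()` solves the thin-film energy balance
`(F/b)^2/(2dE) + (F/b)(1 - cos theta) - R = 0` for the peel force, using
the cancellation-free root form (stable in the inextensible limit, where
F tends to `bR` at 90 degrees and `bR/2` at 180 degrees). Adhesion energy
is accepted in J/m^2 and converted once (1 J/m^2 = 1e-3 N/mm). The force
decreases strictly with the peel angle — pulling at more than 90 degrees,
as dorsodistal septum loading does, is the cheap way to detach.

The contact-stress comparison loads the same elastic block two ways with
equal force magnitude (3.815 mN by default): via a cross-lateral nodal
line on the dorsal face at the septum's ventral attachment, pulled
dorsodistally at 70 degrees above the ventral plane (90 degrees minus the
~20 degree rotation of the septum plane; configurable 60–80), or via a
tensile pull on the proximal end face. Normal contact stress is
operationalised as the z-component of the reaction traction on the fixed
ventral face divided by nodal tributary areas, tension positive; both the
tensile-only and the signed mean are reported since the original
averaging convention is unknown.

One design choice here deviates from the obvious default and matters: the
comparison runs on a **pad-scale block** (`peel_pad_domain()`, 0.9 mm
high — roughly the whole digital pad) rather than on the 0.45 mm collagen
layer model. On the thin slab, the traction field under the attachment
line is a near-field singularity a fraction of a millimetre above the
interface and dominates the ventral tractions for every admissible angle
and attachment position, hiding the peel lever entirely. At pad scale the
line load is remote from the interface, the block responds plate-like,
and the horizontal component of the dorsodistal pull concentrates tensile
traction at the proximal edge — robustly across the tested angle and
position ranges. The septum attachment defaults to just distal of the
duct field, consistent with the ducts draining the gland space on the
proximal side of the septum.

## What the synthetic geometry does and does not emulate

The parametric generator plays the role of the data: every model input is
a printed constant (dimensions, spacings, material constants, load,
schedule, section areas). What it reproduces faithfully is the *design
space* of the published optimisation — box, ducts, recess, symmetry — and
the budget arithmetic. What it does not emulate: the curved anatomical
outline of a real pad, the true (unpublished) recess geometry, partial
voxel volumes at hole boundaries, tissue anisotropy and viscoelasticity,
lymph-space hydraulics, and muscle activation. Passing tests therefore
demonstrate that an optimal stiff structure under the published loading
develops the observed morphological motifs — not that the model predicts
absolute stresses in living tissue; the printed force estimates are
arithmetic bounds, and the FEA-level claims are checked as signs and
trends, never as magnitudes.

## Degenerate inputs and tie-breaks

Geometries with overlapping holes or footprints exceeding the box are
rejected at construction. Resolutions leaving fewer than two voxels
across a hole diameter warn (error in strict mode). Fully void domains
and load cases without constraints produce explanatory errors rather than
singular factorisations. In the ridge profile, runs of equal density are
collapsed to plateaus with the extremum reported at the plateau centre,
so a constant profile has no internal extrema. The optimality-criteria
bisection treats vanishing sensitivities through a 1e-30 floor, which
makes the uniform-sensitivity case reduce to pure volume scaling (the
fixed-point property of the update).
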