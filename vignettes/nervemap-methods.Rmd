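---
title: "Methods: phantoms, morphometry, co-registration, and cuff-electrode models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantoms, morphometry, co-registration, and cuff-electrode models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervemap)
```

nervemap implements the computational stages of a multi-modal peripheral
nerve mapping workflow: quantifying fascicular morphology from segmented
imagery, co-registering cross sections between modalities, reshaping a
segmented cross section into a cuff-electrode volume-conductor model, and
computing extracellular stimulation thresholds and recruitment curves for
myelinated fibers. Because the package is exercised entirely on synthetic
phantoms, every algorithm ships with a seeded generator that produces its
inputs together with the ground truth needed to test it.

## Synthetic phantoms

`phantom_spec()` fixes the study conditions for a phantom: a nerve of
roughly 2 mm effective diameter holding a handful of elliptical fascicles
(axis ratio capped at 2:1, as strongly elongated fascicles are not seen in
transverse sections), a perineurium ring whose thickness is a fixed
fraction (default 0.08) of the fascicle radius, microCT-like 11.4 µm
voxels for 3D label volumes, and few-micron rasters for 2D masks. Fascicle
placement is rejection sampling under a minimum-spacing constraint with a
fixed cap of 10 000 attempts; larger fascicles are placed first, which
makes dense packings reachable without changing the seeded, deterministic
character of the generator. Randomness is split into per-purpose streams
(placement, diameters, orientation, warp, fibers, trace) derived from one
master seed, so requesting a fiber population cannot perturb the geometry.

Fiber populations emulate segmented myelinated fibers: per-fascicle counts
are Poisson in the endoneurial area at a default density of 5000
fibers/mm², and diameters follow a two-component Gaussian mixture (70%
around 4 µm, 30% around 9 µm) that mimics the small-myelinated-dominated
composition of autonomic nerves. These defaults are deliberately generic:
no claim is made that they estimate any particular nerve's empirical
diameter distribution.

Split/merge label volumes extrude circular fascicle tracks along z
(superior to inferior) and realize each scheduled event over a 10-voxel
transition zone in which the child (or parent) profiles separate or
approach linearly. Because the separation is monotone, the
connected-component count changes exactly once per event, which is what
ties the generator's schedule to the slice-overlap definition of an event
used by the detector.

Modality pairs for registration carry a binary fascicle mask through a
similarity transform — the `scale` argument is the moving/fixed content
size ratio, so `scale = 0.915` makes the moving fascicles 8.5% smaller —
plus a band-limited sinusoidal displacement field expressed in the fixed
frame. The backward (moving-to-fixed) map is closed form and is what
rasterizes the moving mask; the forward map is recovered by fixed-point
iteration to 10⁻⁹ µm. Displacement fields whose Jacobian is not positive
everywhere are rejected rather than silently folded.

What the phantoms do not emulate: staining variability, imaging noise and
texture, segmentation errors, non-elliptical fascicle outlines, or
branching anatomy beyond scheduled splits and merges. Passing tests
therefore demonstrate correctness of the algorithms on clean geometry, not
robustness to real segmentation artifacts.

## Morphometry

All diameters are *effective circular diameters*, `2 sqrt(A / pi)` — the
diameter of the circle with the region's area — so values are invariant to
rotation and boundary irregularity. Perineurium thickness is defined
area-equivalently as half the difference between the outer and inner
effective diameters; a local-normal-distance definition would depend on
where the normal is erected, while this one composes exactly with the
package's diameter convention.

Split/merge detection builds, for each consecutive slice pair, the
bipartite overlap graph of foreground connected components
(4-neighbourhood). A component with two or more successors is a split;
two or more predecessors, a merge. One shared voxel counts as overlap, but
components below 5 voxels are ignored to suppress raster artifacts; both
thresholds are arguments. The event rate is normalized by
`(slices − 1) × voxel size`. This overlap-graph event definition is this
package's stated convention — sensible alternatives (e.g. requiring a
fractional overlap) exist, and the threshold is exposed for that reason.

Centerlines are per-slice centroids of a label linked along z and smoothed
with a 5-slice moving average (enough to remove single-voxel centroid
jitter without displacing features materially); arc length accumulates
point spacing. Transverse reslicing erects the plane orthogonal to the
local tangent and samples labels by nearest neighbour at the native voxel
size. This is a deliberately simple stand-in for full skeleton-based
centerline extraction: it is exact for tubular labels, which is what the
phantoms provide, and it suffices to demonstrate the foreshortening
correction (an obliquely cut tube's native slice overestimates its
effective diameter; the transverse reslice recovers it).

Conventions, stated once: label arrays are ordered (z, y, x); voxel
indices are 0-based in physical formulas, with voxel centers at
`index × voxel size`; geometry is in micrometres.

## Co-registration

The coarse tier uses metadata only. Stylus traces are trimmed greedily to
a minimum spacing and fitted per-coordinate with least-squares cubic
B-splines over normalized chord length; landmark positions are cloud
centroids; 3D rigid landmark alignment is the Kabsch/SVD solution;
positions between anatomical levels transfer by preserving the fractional
superior-inferior distance between bracketing levels; histology slides map
to microCT slices via block gridline annotations plus depth divided by
voxel size.

The refinement tier registers binary fascicle masks. Both masks are
standardized first: centers of mass aligned, field of view set to the
larger tissue bounding box plus a 15% margin per side (the margin rule is
interpreted per side, which keeps the field symmetric), and resampled to
3 µm. The rigid/similarity stage minimizes mean squares on the
linearly-interpolated {0,1} images — binary masks need sub-pixel gradients
for gradient descent to converge — with a regular-step gradient descent:
steps are taken along the scale-weighted gradient direction, normalized in
the scaled parameter space (scales 10.0, 1.0, 0.001, 0.001 for scale,
rotation, translations; the scale entry is unused in Euler mode), the step
length starts at 1.0, halves whenever the gradient direction reverses, and
the search stops at a step of 0.01 or 100 iterations. Exhausting the
budget flags the result as non-converged rather than raising, so batch
runs continue. The returned transform maps fixed-frame coordinates to
moving-frame coordinates (the resampling convention); consequently the
similarity `scale` is the moving/fixed content size ratio and
`percent_size_difference()` reports `(1 − scale) × 100` as "smaller".

The non-rigid stage adds an 8×8 grid of cubic B-spline displacement
coefficients over the fixed field of view, initialized at the identity
field on top of the rigid result, and minimizes the same metric with
L-BFGS-B (gradient tolerance 10⁻⁵, 100 iterations, 5 corrections, cost
convergence factor 10⁷; the 1024-evaluation cap is enforced indirectly by
the iteration cap). The metric gradient is analytic — residual times the
warped image gradient projected on the tensor-product basis — which makes
the refinement cost a handful of image interpolations per iteration.

## Reshaping for cuff models

Histological cross sections shrink during fixation and processing;
`inflate_for_shrinkage()` compensates by scaling coordinates about the
section centroid by `1/(1 − s)` with `s = 0.20` by default. Shrinkage is
interpreted as *linear* (diameter) shrinkage: the paper trail behind such
corrections quotes linear factors, and the invariant
`(1 − d_before/d_after) × 100 = 20%` makes the convention auditable. The
areal alternative (scale `1/sqrt(1 − s)`) would inflate areas by only 25%
instead of 56%; anyone preferring it can pass a converted fraction.

`circularize_nerve()` deforms the epineurium to a circle of identical
area (the vertex radius of the 256-gon is inflated so its shoelace area is
exactly the target, making the operation idempotent to floating point),
while fascicles are only translated — never rotated, scaled, or deformed —
which preserves their areas exactly and is the minimal intervention
consistent with displacing fascicles as needed. Feasibility is prechecked
with a hexagonal-packing bound on the gap-padded circumradii. Repacking
then runs in two phases: a boundary-radial projection pulls fascicles that
the original elongated outline placed outside the target circle inward
along their radial direction, and an iterative pairwise relaxation sweeps
fascicles in label order, displacing each violated pair symmetrically
along its centroid-centroid line (radially for boundary violations) by
half the violation plus a 0.5 µm slack, until every gap is at least 10 µm
or the sweep cap (200) is exhausted, which raises a packing error. The
scheme is deterministic and auditable; it makes no claim of mechanical
realism.

The cuff model extrudes the circular section to 50 mm, wraps it in a
100 µm saline film, a silicone cuff, and two platinum ring contacts
(1 mm wide, 1 mm edge-to-edge — the helical clinical contact geometry is
approximated by rings, with the dimensions exposed as configuration, not
asserted as properties of any device), centered about the longitudinal
midpoint, inside a 10 mm × 50 mm muscle cylinder. The 100 µm saline layer
is treated as the binding constraint: the cuff inner diameter always
equals nerve + 200 µm, giving the nominal 3 mm cuff for a 2.8 mm nerve,
expanding for larger nerves and tightening for smaller ones. What happens
at off-nominal nerve diameters is not specified by the source workflow;
this gap-binding rule is the package's own convention.

## Potential fields

The quasi-static extracellular potential obeys ∇·(σ∇V) = −I δ with
anisotropic tissue conductivities (endoneurium and muscle are
longitudinally anisotropic; the full table is `material_table()`). The
solver is a 7-point finite-difference scheme with harmonic face averaging
on a voxelized, reduced, contact-centered domain (default 25 µm voxels;
the pipeline default is 100 µm with the thin-sheet correction), grounded
at the outer boundary, solved by Jacobi-preconditioned conjugate
gradients to a relative residual of 10⁻⁸. It replaces a finite-element
solve; parity with FEM potentials on real anatomies is explicitly not
claimed — the solver's contract is agreement with the anisotropic
point-source closed form on homogeneous benchmarks (within 5% at mid
radii when the boundary is held at the closed-form values) and exact
discrete current conservation.

Two numerical choices matter. First, perineurium much thinner than a
voxel would vanish from the grid; instead the one-voxel ring keeps the
perineurium label and its radial conductivity is scaled by
`voxel/thickness`, preserving the sheet resistance that dominates
threshold behaviour. Second, the raw material table spans 19 orders of
magnitude (silicone 10⁻¹² to platinum ~10⁷ S/m), which no iterative
solver conditions well; voxels below `sigma_floor` (10⁻⁸ S/m) are treated
as perfect insulators and excluded from the domain — exact for silicone —
and conductivities are capped at `sigma_cap` (10³ S/m), which leaves the
platinum contact effectively equipotential. Both clamps are arguments of
`solve_laplace_fd()`.

Potentials are sampled every 1 µm along each fascicle centroid (thresholds
vary little within a fascicle), interpolated linearly to MRG compartment
centers, and superposed across the two contacts in anti-phase under the
symmetric biphasic stimulus (250 µs per phase, 1 ms onset). Which contact
leads cathodically is configurable (`polarity`), since the source
workflow does not pin it down.

## Fiber thresholds and recruitment

The myelinated fiber model is the McIntyre–Richardson–Grill double cable:
node, MYSA, FLUT and six STIN compartments per internode, an explicit
periaxonal pathway under the myelin, fast and persistent sodium plus slow
potassium at the nodes, and passive internodal membranes. Geometric
parameters for 5.7–16 µm fibers come from the published tables bundled in
`mrg_table()`; between rows they interpolate linearly, and below 5.7 µm
each parameter follows a power law fitted through the two smallest rows.
That extrapolation is a package choice: it is positive and monotone down
to 2 µm (a linear extrapolation of internode spacing would go negative
near 3 µm) at the cost of shorter internodes than some published small-
fiber fits; threshold *ordering* across diameters, which is what the
package asserts, is insensitive to this choice.

Integration is backward Euler at a 1 µs step: gates advance
semi-implicitly from the previous voltage, then the linear system in
(membrane, periaxonal) potentials — block-tridiagonal, bandwidth 3 — is
solved with LAPACK's pivoted banded solver. At nodes the periaxonal space
opens to the extracellular medium (implemented as a large myelin
conductance), which is how extracellular gradients polarize the cable.
The default simulated time is 50 ms; threshold searches use 10 ms since
detection happens within a few ms of the 1 ms onset, and the full default
is retained in `sim_settings()`.

Thresholds use bisection: the bracket doubles from 0.01 mA until
activation (capped at 1 A), then narrows until the bounds are within 1%;
the reported threshold is the upper bound, which is guaranteed to
activate. Activation means a rising-edge −30 mV crossing at the node of
Ranvier nearest 90% of the fiber length — far enough from the stimulated
middle to require propagation, and off the fiber end to avoid sealed-end
artifacts. Per-fascicle thresholds computed at 2–16 µm in 2 µm steps are
interpolated across diameter with a least-squares quadratic (exact when
only three diameters are run), mapped to each segmented fiber's diameter
and fascicle, with fibers below 2 µm or above 16 µm excluded and counted,
and summarized as the recruitment curve
`fraction(A) = #{thresholds ≤ A}/N`.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale by choice:
registration phantoms of ~0.6–1.5 mm nerves at 3 µm standardized
resolution, homogeneous solver benchmarks at 41³–61³ voxels, cuff solves
at 100 µm voxels on a 4 × 4 × 8 mm reduced domain, fiber paths of
10–20 mm, and threshold searches at 10 ms. The full chained pipeline is
bit-reproducible for a fixed seed: generators draw from per-purpose
streams, the registration and solver iterations are deterministic, and no
step consults the wall clock or unordered containers.

## Known limitations

Morphometric centerlines assume one dominant component per slice per
label; the split/merge event definition is a convention, not an inference
of the biological branching type; the registration tier handles 2D
sections only (volumetric registration is out of scope); the field solver
is first-order accurate at conductivity interfaces and its absolute
potentials on real cuff geometries are not validated against FEM; MRG
parameters below 5.7 µm are an extrapolation; and thresholds for a real
clinical cuff depend on contact geometry details (helicity, wall
dimensions) that are approximated here by configurable rings.
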