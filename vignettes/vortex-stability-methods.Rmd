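---
title: "Vortex-core stability analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vortex-core stability analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vortexstab)
```

`vortexstab` quantifies how stable the swirling flow inside an intracranial
aneurysm sac is over the cardiac cycle. This vignette explains the model and
its assumptions, the parameters that matter, the numerical choices, what the
synthetic fixtures do and do not emulate, and the design decisions that were
genuinely open.

## Data model and units

The pipeline operates on voxel-centered samples of a 3-component velocity
field on a uniform rectilinear grid: index `(1,1,1)` sits at the grid
origin, axis order is x, y, z, and a component's volume is exactly
`voxel count × spacing³`. Units are fixed package-wide — lengths in mm, time
in s, velocity in mm/s, wall shear stress in Pa — and are recorded in the
`.vti` file metadata and checked at load, because mixing m- and mm-based
exports is the classic failure mode of this kind of post-processing. A
cardiac cycle is represented by an ordered series of such fields (the
reference protocol uses 21 equally spaced phases over a 1 s cycle, i.e. a
60 bpm heart rate) sharing one grid and one validity mask, plus a binary
sac mask registered to the same grid.

## Vortex identification

Per phase, the velocity-gradient tensor `∇u` is estimated by second-order
central differences at voxels whose ±1 neighbors are valid on each axis and
by first-order one-sided differences where only one neighbor is valid;
voxels with no valid neighbor on some axis are excluded. The split
`∇u = S + Ω` into the symmetric rate-of-strain tensor and the antisymmetric
vorticity tensor is exact by construction. Two classic point-wise criteria
follow:

* `Q = (‖Ω‖²_F − ‖S‖²_F)/2`, positive where rotation dominates strain
  (Frobenius norms — the "Euclidean norm" of a tensor);
* `λ₂`, the middle eigenvalue of the symmetric tensor `S² + Ω²`, negative
  inside a vortex.

Both are Galilean invariant. Their *normalized* variants divide by the
squared local speed, `Q̄ = Q/|u|²` and `λ̄₂ = λ₂/|u|²` (units 1/mm²
instead of 1/s²), which condenses the heavy-tailed distribution of raw
criterion values and makes one threshold usable across the whole cycle of a
pulsatile flow: scaling the velocity field by a waveform factor `w` scales
`Q` by `w²` but leaves `Q̄` unchanged. This is why the normalized
Q-criterion is the default method — a pooled threshold then classifies
systolic and diastolic phases consistently, and the package's stationary
pulsatile fixture scores DVO exactly 1 under it.

Division by `|u|²` needs a zero-velocity guard; the package marks voxels
with `|u| < ε · max|u|` (per phase, default `ε = 1e-6`) invalid rather than
assigning them 0, so stagnant voxels can never enter threshold statistics.
The middle eigenvalue is computed with the closed-form trigonometric
symmetric-3×3 solver, fully vectorized over voxels. Its accuracy degrades
to about `√(machine eps)` (~1e-8 absolute per unit magnitude) exactly at
repeated eigenvalues — e.g. rigid rotation, where the spectrum is
`(−ω², −ω², 0)` — which is harmless at the criterion scale and is the
documented precision bound in the tests; a Newton polish cannot improve a
repeated root (the characteristic derivative vanishes there).

Gradients are computed on all valid voxels and the sac mask is applied
*afterwards* (configurable via `mask_before`): sac-boundary stencils then
see the true flow rather than an artificial wall, which is the right
behavior when the mask is an analysis region, not a physical boundary.

## Threshold ladder and segmentation

Within the mask, the qualifying-sign criterion values (positive for Q-type,
negative for λ₂-type) are pooled **across all phases of the case** and
summarized by mean and sample STD. Five candidate thresholds follow, in
ascending order `[mean/4, mean/2, mean, mean+STD/2, mean+STD]` for Q-type
and `[mean−STD, mean−STD/2, mean, mean/2, mean/4]` for λ₂-type methods; the
default working point is `mean`. Pooling per case (rather than per phase)
is a deliberate choice: one fixed iso-level underlies every phase's
structure *and* the cycle-averaged structure, so DVO measures flow change,
not threshold change. Per-phase alternatives remain possible by calling
`criterion_statistics` on single phases.

Binarization is strict (`value > threshold` for Q-type, `<` for λ₂-type);
components are labeled with 26-neighbor connectivity (the permissive
standard for sparse 3-D structures — face, edge or corner contact joins
voxels), and components below 0.5 mm³ are discarded to suppress small
spurious islands. The comparison defaults to `≥ 0.5 mm³` and is
configurable, since both strict and inclusive readings of the cutoff are
defensible; at 0.2 mm spacing the cutoff sits between a 62-voxel
(0.496 mm³) and a 63-voxel (0.504 mm³) component. Core counting and all
volumes are voxel-based and deterministic. Iso-surfaces are extracted only
for export and visualization, by marching tetrahedra (each cell split into
six tetrahedra around the main diagonal, linear interpolation on edges,
consistent outward orientation, domain padded so surfaces close); the
enclosed divergence-theorem volume they report typically agrees with the
voxel-count volume to ~1–2% at 0.1 mm spacing and is never used for
counting.

## Stability metrics

The cycle-averaged structure is built from the voxelwise arithmetic mean of
the criterion field over phases (a voxel's mean uses the phases where it is
valid; it is invalid only if invalid everywhere), thresholded and filtered
at the same case threshold. The Degree of Vortex Overlap between a phase's
structure and the averaged one is the **Jaccard index** on the post-filter
voxel sets. The overlap measure itself was an open choice; Jaccard is
symmetric, bounded in [0, 1], equals 1 iff the sets are identical and 0 iff
they are disjoint, and the Dice coefficient is available behind
`overlap = "dice"` for sensitivity checks. Empty-set conventions: if exactly
one of the two sets is empty the DVO is 0 (a vanished vortex is maximal
instability); if both are empty it is undefined (`NA`) and excluded from
the mean.

A case is summarized by mean ± sample STD (n−1 throughout) of the per-phase
DVO, of the per-phase retained-core counts, by the coefficient of variation
of the counts `(STD/mean)·100` (flagged undefined when the mean count is 0
— phases without coherent cores reduce the mean and inflate the STD, which
is precisely how count instability shows up as CoV near or above 100%),
and by the mean total vortex volume. `voxel_size_sweep` re-runs the whole
pipeline after trilinear resampling to each requested spacing: fine grids
fragment structures (components can fall below 0.5 mm³), coarse grids blur
them into fewer, fatter cores, so resolution is itself an analysis
parameter; 0.2 mm is the reference working point.

## Resampling and voxelization

Resampling is trilinear only — the probe-filter style of resampling this
field uses is linear, and higher-order schemes would manufacture smoothness
claims the data cannot support. A target voxel is invalid whenever its
8-corner stencil touches any invalid or out-of-bounds source voxel: no
extrapolation, no clamping, so near-wall velocities are never fabricated.
How partially-filled wall voxels should be treated is not standardized;
this invalidation rule is the package's choice and errs toward discarding
data rather than inventing it. Surface-to-mask voxelization uses x-ray
parity on watertight, consistently oriented triangulations, with a tiny
constant ray offset so rays cannot pass exactly through mesh edges; the
offset is shared by all rays, preserving translation equivariance by whole
voxels.

## Wall metrics and geometry

TA-WSS averages the WSS *magnitude* over phases per vertex (direction
reversals must not cancel); STA-WSS spatially averages TA-WSS over the
wall. OSI is `½(1 − |Σₜ τ| / Σₜ |τ|)` with plain sums over the T phase
samples — with uniform phase spacing the Δt of the underlying integrals
cancels in the ratio; a trapezoidal option exists. Vertices with zero total
shear are undefined and excluded from SA-OSI. Spatial averages are
unweighted by default (the simplest reading of "spatial averaging"), with
area weights accepted since mesh vertex densities vary.

Sac geometry from a sealed mesh with labeled ostium-cap faces: volume by
the divergence theorem, ostium area as the cap face-area sum, circumference
as the cap boundary-loop length, height as the distance from the cap area
centroid to the farthest dome vertex, aspect ratio as height over the
widest ostium diameter (exact maximum pairwise distance among cap boundary
vertices — O(n²) is fine at this scale). Note a consequence of the
farthest-point height definition: a pancake-flat sac is rim-dominated
(height ≈ ostium radius, aspect ratio ≈ 0.5); height does not tend to zero
with sac depth.

## Case statistics

Pearson correlations report the sample coefficient with the two-sided
p-value from `t = ρ√(n−2)/√(1−ρ²)` on n−2 df (perfect correlations are
floored at the smallest positive double rather than p = 0). The two-sample
t-test defaults to Welch's unequal-variance form — group spreads of the
quantities involved are routinely unequal — with pooled Student's t behind
a flag; two zero-variance groups with equal means give `t = 0, p = 1` by
convention, with different means they are flagged degenerate. Bland–Altman
agreement uses direction `b − a`, bias ± 1.96·STD limits (the exact-t
small-sample multiplier is behind a flag), and raw p-values are reported
without multiple-testing correction by default, matching the convention of
reporting uncorrected correlation tables; Benjamini–Hochberg is available
in `pearson_table`.

## What the synthetic fixtures emulate — and what they do not

The generator produces: solid-body rotation (exact positive control —
`Q = ω²`, `λ₂ = −ω²`, affine in position so finite differences and
trilinear resampling are exact); plane shear (exact null control — `Q` and
`λ₂` identically zero); Lamb–Oseen vortices `u_θ(r) = Γ/(2πr)(1−e^{−r²/r_c²})`
(the canonical compact-core vortex: both criteria change sign at a finite
radius, giving a nontrivial segmentation target; peak tangential speed at
`r ≈ 1.121 r_c`), singly, in pairs, drifting along a per-phase path, and
modulated by a positive pulsatile waveform (default `1 + 0.5 sin`, 21
phases); hemispherical / half-ellipsoidal sealed sac meshes with labeled
ostium caps and matching voxel masks; WSS series with controllable
reversal; optional seeded Gaussian velocity noise to emulate solver
differences in agreement exercises.

Default fixture scale: 48³–64³ voxels at 0.2 mm, `Γ = 40 mm²/s`,
`r_c = 0.8–1 mm`, sac radii 4–5 mm — sized like a small cerebral aneurysm
and small enough that the full test suite and the acceptance script run in
minutes on one CPU.

These fixtures validate the *measurement machinery* exactly: criterion
algebra, segmentation determinism, overlap arithmetic, closed-form wall
and geometry values. They do **not** emulate real intra-aneurysmal flow —
no secondary flow structures, no wall-bounded boundary layers, no inflow
jet, no solver discretization error beyond optional white noise, and sac
shapes are idealized. Passing tests therefore demonstrate correctness of
the analysis, not clinical validity of the stability metrics on patient
data.

## Known limitations

* Threshold position and voxel resolution both materially change core
  counts and DVO; they are exposed as explicit parameters, and the ladder
  and sweep utilities exist precisely to report that sensitivity rather
  than hide it.
* The λ₂ eigen-solver's precision floor at repeated eigenvalues is ~1e-8
  relative; irrelevant in practice but visible in exactness tests.
* Voxelization counts a voxel as inside when its center is inside; surfaces
  passing exactly through voxel-center planes are knife-edge cases where a
  boundary layer resolves entirely to one side (fixtures avoid lattice
  coincidence for this reason).
* No vortex-core-line extraction and no tracking of individual core
  identity across phases: stability is measured through counts and overlap
  with the cycle average only.
* Unstructured-mesh CFD output must be resampled to a rectilinear grid
  upstream; the package starts at the rectilinear representation.
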