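# vortexstab

Vortex-core identification and temporal stability analysis for
intra-aneurysmal flow.

## The problem

Blood flow inside an intracranial aneurysm (IA) sac is dominated by swirling
recirculation. How *stable* that swirl is over the cardiac cycle — whether
one coherent vortex persists, or cores form, drift and vanish between
systole and diastole — is a candidate hemodynamic marker that is largely
independent of the usual geometric (volume, aspect ratio) and wall-shear
(WSS, OSI) descriptors. `vortexstab` post-processes time-resolved 3-D
velocity fields on rectilinear voxel grids (CFD results resampled to a
uniform grid, or in principle PC-MRI data) and quantifies that stability.

## The method

For each cardiac phase the velocity-gradient tensor is split into the
rate-of-strain tensor `S = (∇u + ∇uᵀ)/2` and the vorticity tensor
`Ω = (∇u − ∇uᵀ)/2`. Vortex-core regions are identified by

* **Q-criterion** — `Q = (‖Ω‖²_F − ‖S‖²_F)/2 > 0` (rotation dominates strain),
* **λ₂ method** — the middle eigenvalue of `S² + Ω²` is negative,

optionally normalized by the squared local speed (`Q̄ = Q/|u|²`,
`λ̄₂ = λ₂/|u|²`), which condenses the dynamic range before thresholding.
Within the aneurysm-sac mask, an iso-level is chosen from a five-position
threshold ladder built from the mean and STD of the qualifying-sign
criterion values (`[mean/4, mean/2, mean, mean+STD/2, mean+STD]` for Q-type
methods); the super-threshold voxels are labeled into 26-connected
components and components smaller than 0.5 mm³ are discarded. Temporal
stability is summarized by

* **DVO** (Degree of Vortex Overlap): the Jaccard overlap in [0, 1] between
  each phase's vortex structure and the structure extracted from the
  cycle-averaged criterion field (1 = perfectly stationary swirl), reported
  as mean ± STD over the 21 cardiac phases, and
* the per-phase **core count**, reported as mean ± STD and as a coefficient
  of variation `(STD/mean)·100`.

Companion computations: marching-tetrahedra iso-surfaces for export, wall
metrics (per-vertex TA-WSS, STA-WSS, OSI `= ½(1 − |Στ|/Σ|τ|)`, SA-OSI), six
sac-geometry metrics from a sealed surface mesh with a labeled ostium cap,
and the cross-case statistics (Pearson correlation with p-values, Welch
t-tests, Bland–Altman agreement with 1.96·STD limits).

Because no patient data ship with the package, a synthetic-flow module
generates analytic fixtures with known ground truth — solid-body rotation,
Lamb–Oseen vortices (single, paired, drifting), plane shear, pulsatile
waveforms, hemispherical sac meshes/masks and WSS series with controllable
reversal — so the whole pipeline is testable end to end.

## Worked example

A single Lamb–Oseen vortex (circulation 40 mm²/s, core radius 0.8 mm) whose
center swings ±0.6 mm over a 21-phase pulsatile cycle, inside a
hemispherical sac of radius 4.2 mm on a 48³ grid at 0.2 mm:

```r
library(vortexstab)

grid <- voxel_grid(origin = c(-4.73, -4.73, -4.73), spacing = 0.2,
                   dims = c(48, 48, 48))
sac  <- make_sac_mesh("hemisphere", radius = 4.2, center = c(0.03, 0.05, -2.07),
                      grid = grid, n_seg = 64)
drift  <- cbind(0.6 * sin(2 * pi * (0:20) / 21), 0, 0)
spec   <- flow_spec("lamb_oseen", circulation = 40, core_radius = 0.8,
                    drift_path = drift)
series <- make_series(spec, pulsatile_waveform(21), grid)

fit <- vortex_stability(series, sac$mask, method = "Q_norm")
fit
#> Vortex-core stability analysis (Q_norm criterion, jaccard overlap)
#>   phases: 21; threshold: 5.58064 (mean of the ladder)
#>   mean vortex volume: 1.900 mm^3
#>   number of cores:    1.00 +/- 0.00  (CoV 0.0%)
#>   DVO:                0.328 +/- 0.065
```

One coherent core persists through the cycle (count 1, CoV 0%), but the
drift keeps each phase's core from overlapping the cycle-averaged structure
(mean DVO 0.33): a spatially unstable but topologically stable vortex. The
same vortex without drift gives DVO exactly 1 at every phase. Sac geometry
comes from the sealed mesh:

```r
geometry_metrics(sac$mesh)
#> Aneurysm sac geometry
#>   volume:                154.827 mm^3
#>   ostium area:            55.329 mm^2
#>   ostium circumference:   26.379 mm
#>   height:                  4.200 mm
#>   aspect ratio:            0.500
#>   volume/ostium area:      2.798 mm
```

`summary(fit)` gives the per-phase table, `plot(fit)` the DVO and
core-count traces, and `voxel_size_sweep(series, sac$mask, c(0.1, 0.2, 0.4))`
re-runs the pipeline across voxel resolutions.

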