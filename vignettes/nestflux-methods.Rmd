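---
title: "Curvature, evaporation and collective construction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature, evaporation and collective construction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestflux)
```

# The scientific problem

Early nest construction by *Coptotermes* termites in a flat experimental
arena shows a striking asymmetry: pellet *collections* are spread roughly
wherever termites happen to be, while pellet *depositions* concentrate on a
few privileged locations — the tips of pre-made topographic cues (pillars, a
wall) and the rim of the humid clay disk. Two physical quantities co-vary at
exactly those places: the local mean curvature of the substrate surface, and
the evaporation flux leaving it. For a substrate drying by quasi-static
vapor diffusion the two are in fact proportional (for a sphere of radius
$R$, the classical result that evaporative flux scales as $1/R$), so
curvature sensed *through* evaporation is a single, parsimonious stigmergic
cue. The one place where the two cues separate is the disk edge: nearly flat
for a walking termite, but a wet-dry contact line where evaporation is
strongly enhanced — the same mechanism that deposits a coffee ring.

`nestflux` implements the computational side of that argument as four
cooperating components:

1. **Scene geometry** — parametric arenas (disk, pillars, wall, pellet
   band) rasterized to elevation maps and voxel occupancy grids, plus a
   reader for scanned surface meshes (`buildHeightMap()`, `voxelize()`,
   `loadScanMesh()`).
2. **Growth model** — a phase-field simulator in which construction speed
   is proportional to local surface curvature (`initializeField()`,
   `runGrowth()`, `depositionVoxels()`, `projectAndProfile()`).
3. **Humidity solver** — the steady diffusive humidity field over a scene,
   its gradient magnitude and surface evaporation flux
   (`solveLaplace()`, `gradientMap()`, `surfaceFlux()`).
4. **Image pipeline + synthetic timelapse** — the analysis that turns
   building timelapses and tracked trajectories into collection/deposition/
   occupancy probability maps (`detectChanges()`, `extractEvents()`,
   `occupancyMap()`, `conditionalMap()`), and a seeded generator of ground-
   truth timelapses that makes the pipeline testable end to end
   (`renderSequence()`, `stimulusField()`).

All lengths are in millimetres; the arena center is the origin, z points up.

# The growth model

## The law

The state is an order parameter $f \in [0,1]$ on a regular voxel grid, 1 in
the nest material and 0 in the air; the built surface is the $f = 0.5$ level
set. Writing $K = -\Delta f$ (a discrete curvature density, positive over
convex solid features) the update is the explicit Euler integration, in
lattice units, of

$$\frac{\partial f}{\partial t} = f(1-f)\,\bigl(d\,K + \Delta K\bigr).$$

The three ingredients are: a *growth term* $d\,K$ — convex solid accretes,
concave solid erodes, which is the curvature-deposition hypothesis and also
reproduces the observed attraction of digging to concavities; a *curvature
diffusion term* $\Delta K$ that relaxes curvature variation and imposes a
short-wavelength cutoff (pellets have a finite size; termites smooth); and
the prefactor $f(1-f)$ that confines dynamics to the interface. A
small-slope analysis of a nearly flat interface gives the growth rate
$\sigma(k) = d\,k^2 - k^4$: structure emerges spontaneously with fastest
wavelength $\lambda^* = 2\pi\sqrt{2/d}$ voxels, and $d$ alone selects the
pattern scale.

Initially solid voxels with smoothed $f > 0.85$ are frozen for the whole
run: dried structures are never re-worked, and the pre-existing template can
only gain material at its surface.

## Numerical choices

* **Stencils.** 7-point Laplacian, applied twice for the biharmonic part;
  zero-flux (mirror) ghost cells on all domain faces.
* **Time step.** Explicit Euler with the biharmonic-dominated bound
  $\Delta t \le 1/\bigl(8(d+4)\bigr)$ (lattice units), enforced by the
  `GrowthParams` validity method; the default uses 90% of the bound.
  Boundedness of $f$ under this step is asserted by a property test on
  noise-perturbed fields.
* **Initialization.** The binary mask is unsharpened by a Gaussian filter
  (default $\sigma$ = 1.5 voxels). A *binary* flat slab is an exact fixed
  point of the discrete law; a *smoothed* flat profile first undergoes a
  small, sum-preserving shape relaxation (order $10^{-2}$ in $f$) that does
  not move the interface — the stationarity tests distinguish these two
  statements.
* **Degenerate inputs.** All-solid or all-air masks are rejected; NaN
  during a run aborts with the step number; mismatched grids are rejected
  by `depositionVoxels()`.
* **Level-set convention.** "Solid" is $f \ge 0.5$, ties toward solid.

## Lattice scale and the dimensionless end time

The law is integrated in lattice units, so at fixed physical pattern scale
the dynamics slow down as the grid is refined (the $\Delta K$ term scales as
$\mathrm{d}x^{-4}$). The reference simulations show substantial growth on
the cue tips by the dimensionless end time $t = 9$, which pins the regime:
the pattern scale must span roughly half a dozen voxels. The growth stage
therefore runs on a 0.45 mm lattice (the 3 mm cue scale is 6–7 voxels)
where $t = 9$ moves the interface by 1–2 voxels at the tips; a full pillar
run takes seconds. The humidity solver, which has no such scaling, runs on
a finer 0.2 mm grid.

## Calibrating d

The only free parameter is calibrated, not assumed: `calibrateD()` seeds a
flat slab with small interface noise, integrates each candidate $d$ long
enough to amplify its fastest mode by a fixed factor (compensating the
initial Gaussian damping of that mode), measures the dominant wavelength as
the radial spectral peak of the interface height, and picks the candidate
whose wavelength is nearest the 3 mm cue thickness. Emergent wavelengths
run ~1.4× above the small-slope prediction (finite interface width and
lattice dispersion), which is precisely why the empirical sweep is used.
The sweep is deterministic given its seed, and monotonicity of scale with
$d$ is a property test.

# The humidity solver

In the diffusive boundary layer, vapor transport is quasi-static diffusion,
so relative humidity $h$ solves $\Delta h = 0$. The domain is an 18 mm cube
whose bottom face is replaced by the (voxelized) scene; boundary conditions
are $h = 100\%$ on every air-voxel face adjacent to wet solid, $h = 70\%$
(typical room humidity) at the top plate, and zero flux on the lateral
walls. Temperature is taken constant, so relative and absolute humidity are
proportional and $|\nabla h|$ is reported in mm$^{-1}$ on the fraction
scale (a 30% drop over 2 mm is 0.15 mm$^{-1}$).

Numerically this is a matrix-free conjugate-gradient solve of the 7-point
stencil over the air voxels (C++ kernel), to relative residual $10^{-8}$.
Dirichlet values act on voxel *faces* — half-spacing links with coefficient
2 — which makes the empty-floor solution exactly linear and face-flux
conservation exact; the flux-balance test (total surface flux = top-plate
flux within 1%) then checks the solver, not the bookkeeping. A flood fill
rejects air regions that cannot reach the top plate. For isolated-droplet
oracles the solver accepts a far-field shell held at the top-plate value,
and the concentric-shell closed form provides the analytic reference: the
computed field matches within 2% and the fitted flux exponent over a decade
of radii is $-1.0$, the Maxwell law.

Derived maps: `gradientMap()` uses distance-aware centered/one-sided
differences (Dirichlet faces at half spacing); `surfaceFlux()` reports the
outward face gradient per surface voxel, up to the constant diffusivity
factor that is deliberately not modeled. The headline statistics are
`amplification()` — max $|\nabla h|$ within 2 mm of a cue tip over the
median at the flat disk 8–15 mm from center — and `wallEdgeStats()`, which
profiles the wall's top edge per grid column and reports the lateral-tip
maximum, the mid-edge plateau median, and the corner/mid ratio computed on
the 3-column smoothed profile (single corner voxels are
discretization-sharpened; contour-map levels are read at feature scale).
The box-profile wall used here is a stand-in for the hand-molded clay wedge
of the real setup, which is why the mid-edge plateau sits toward the lower
end of its tolerance band.

# The image pipeline

The pipeline mirrors a change-detection analysis of building timelapses:

1. subsample to the 80 s search–collection–deposition timescale
   (`extractFrames()`);
2. convert to greyscale, subtract the animal-free reference frame, and take
   a trailing temporal median over 10 frames — anything that keeps moving
   (termites) vanishes, anything that changed once and persists (a moved
   pellet) survives (`detectChanges()`, valid mode: the first 9 frames
   yield no output);
3. average blocks of 10 median images into 800 s activity windows;
4. binarise at a low threshold (default $3\times$ the MAD of the
   background-subtracted frame intensities), label connected components, and keep areas in the closed interval
   [10, 400] px — below is noise, above is a cluster of resting animals
   (`extractEvents()`; collections are dark traces, depositions bright);
5. bin component mass onto the 0.75 mm analysis grid (one cell = one
   pellet) per window and cumulatively (`accumulateEvents()`); tracked
   positions are binned the same way for occupancy (`occupancyMap()`).

Maps are normalized by their mean (`normalizeByMean()`), so values read
directly as enrichment over chance; conditionals are cellwise ratios
$P(D|O) = P(D)/P(O)$ masked where occupancy is too low
(`conditionalMap()`), and satisfy the exact identity
conditional × occupancy = activity on valid cells. `radialDensity()`
(per-annulus-area, sums to 1) and `crossSection()` (max-normalized cut)
produce the 1D summaries used for cross-method comparison; `compareCut()`
aligns measured depositions, surface curvature and simulated depositions on
one cut and reports their peaks.

# The synthetic timelapse generator

`renderSequence()` renders the study conditions rather than arbitrary
scenes: an 85 mm arena with a 50 mm clay disk, 0.12 g-scale loose pellet
inventory as a band of 0.75 mm pellets halfway between disk center and rim,
50 workers plus 5 soldiers as 4 × 1.5 mm elongated blobs, frames at 20 s
cadence, Gaussian pixel noise. Collections remove an existing pellet chosen
uniformly (the observed collection behavior); depositions add a pellet at a
location sampled with probability $\propto$ stimulus$^\alpha$, where the
stimulus field is either projected surface curvature or the humidity
gradient (`stimulusField()`) — the two agree on cue tips and differ only on
the disk-edge ring, so the generator encodes the discriminating prediction.
$\alpha$ is a free synthetic parameter (the study gives no quantitative
choice function); $\alpha = 4$ concentrates deposits as sharply as the
observed maps. Everything is driven by one seed and is bitwise
reproducible.

Blob motion is a persistent-heading walk of 2 mm per frame with reflective
arena walls: fast enough that a blob clears its own footprint between
80 s analysis frames, which is what lets the temporal median suppress it.
For even-length windows the median is taken as the upper central order
statistic: animals only ever darken a pixel, so a strict majority of dark
samples is required before the filter output turns dark. Even so, with 55
animals wandering uniformly, six independent co-visits of the same pixel
within ten analysis frames occur somewhere in the arena on the order of
once per few runs, and such a coincidence is indistinguishable from a real
pellet trace; the null-sequence check is therefore a seeded, deterministic
fixture, and sporadic single-speck false positives remain possible for
arbitrary seeds (as they are for real multi-animal footage).
Pellet contrast (0.3 against the clay) places the default detection
threshold several noise standard deviations below an event's amplitude.

What the generator does *not* emulate — and therefore what passing tests do
not certify on real data: perspective and illumination drift, misaligned
frames, pellet occlusion by termites at the moment of reading, partial
pellet displacements, reflections at the dish wall, and any behavioral
feedback of deposits on later movement. The pipeline-closure tests
(≥ 95% of planted events recovered within one cell; zero events on a
null sequence) validate the analysis logic, not the camera.

# Problem sizes and determinism

The shipped analyses use: 0.2 mm humidity grids (90³ cube, conjugate
gradients converge in a few hundred iterations, seconds per scene); a
0.45 mm growth lattice (40³, ~500 steps to $t = 9$, seconds); calibration
on an 84 × 84 × 24 slab (seconds per candidate); synthetic timelapses of
117 frames at 567² px (about 30 s to render and analyze). Every stochastic
stage takes an explicit seed; PDE stages are deterministic, so reruns with
the same configuration are bitwise identical. `reproduceTargets()` runs the
whole chain from a validated config and returns the headline numbers;
`scripts/acceptance.R` is a thin wrapper around the same calls.

# Known limitations

* The growth law is phenomenological: time is dimensionless, no mapping to
  wall-clock building time is attempted, and absolute deposition volumes
  are not predictions.
* Voxelized (staircase) surfaces limit pointwise surface statistics;
  extreme-value statistics near sharp corners are resolution-sharpened,
  which is why corner comparisons use feature-scale smoothing and why
  convergence tests probe smooth-region fields.
* The wall and pillar cues are ideal box/cylinder profiles with a smoothing
  ramp, stand-ins for scanned hand-molded clay; absolute edge-gradient
  levels inherit that geometric idealization.
* The humidity model is pure diffusion at constant temperature: no
  convection, no evaporative cooling, no capillary transport inside the
  clay.
* Frozen voxels still contribute geometry to the curvature stencil; they
  are immutable but not invisible.
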