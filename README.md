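# nestflux

Computational tools for studying how substrate geometry organizes
collective construction on humid substrates, motivated by early
nest-building in *Coptotermes* termites. In the underlying picture, pellet
depositions concentrate where the evaporation flux from the wet clay
substrate is largest, and in the diffusive regime that flux is proportional
to the local mean curvature of the surface — so the shape of the structure
itself is the building cue. The package provides:

* **Scene geometry** — parametric arenas (clay disk in a Petri dish, pillar
  or wall cues, pellet band) rasterized to elevation maps and 3D voxel
  masks, plus an ASCII STL/OBJ/PLY reader that voxelizes surface-scan
  meshes by orientation-independent ray parity.
* **Growth model** — a curvature-driven phase-field simulator,
  `df/dt = f(1-f) (d K + ΔK)` with `K = -Δf`: convex solid accretes,
  curvature variation relaxes, initially dried material is frozen. The
  pattern-scale parameter `d` is calibrated against the 3 mm cue scale by a
  spectral sweep on a noisy flat interface.
* **Humidity solver** — steady-state diffusive humidity (`Δh = 0`) over a
  voxelized scene in an 18 mm cube (100% at the wet surface, 70% at the top
  plate, no-flux sides), solved matrix-free by conjugate gradients in C++;
  gradient-magnitude maps in mm⁻¹, per-voxel surface evaporation flux, tip
  amplification and wall-edge statistics. A far-field shell mode reproduces
  the Maxwell droplet law (flux ∝ 1/R) against the closed form.
* **Image pipeline** — timelapse change detection (background subtraction,
  temporal median over 10 frames, 800 s windows), connected-component event
  extraction with the [10, 400] px area filter, and gridded
  collection/deposition/occupancy maps at 0.75 mm with mean normalization,
  conditionals P(D|O) = P(D)/P(O), radial densities and cross-sections.
* **Synthetic timelapse generator** — seeded ground-truth renders of the
  study conditions (50 workers + 5 soldiers, pellet band, planted
  collection/deposition events placed by a curvature or humidity-gradient
  stimulus field), so the whole pipeline is testable end to end without the
  original videos.

## Worked example

Solve the humidity field over the two-pillar arena and ask how much the
pillar tips concentrate the evaporative gradient relative to the flat disk:

```r
library(nestflux)

spec <- sceneSpec("pillars")      # 50 mm disk, pillars 6 mm high, 8 mm apart
hm   <- buildHeightMap(spec, spacing = 0.2, extent = 11)
mask <- cropToCube(voxelize(hm, 0.2), side = 18)
hf   <- solveLaplace(mask, domainHeight = 18)   # h = 100% surface, 70% top
gm   <- gradientMap(hf)

amplification(gm, tipRegion(mask, 2), flatReferenceRegion(mask, 8, 15))
#> [1] 9.100668
```

The ratio ~9 means the humidity gradient at the pillar tips is about nine
times the flat-disk reference — the tips are evaporation hotspots, matching
the roughly tenfold amplification inferred from the diffusive simulations
of the original study. Running the curvature-driven growth model on the
same scene and profiling where material is added:

```r
cal <- calibrateD(0.45, seed = 1)       # pattern scale -> 3 mm cue thickness
gp  <- growthParams(d = cal$d, tEnd = 9, smoothingSigma = 1.5 * 0.45)
hmG <- buildHeightMap(spec, 0.45, extent = 11)
pf0 <- initializeField(cropToCube(voxelize(hmG, 0.45), 18), gp)
run <- runGrowth(pf0, gp)
prof <- projectAndProfile(depositionVoxels(pf0, run[["t=9"]]), pf0)
profilePeak(prof)
#> [1] 4.25
```

Simulated depositions peak at a radius of ~4 mm — the pillar tips — the
same place the measured deposition maps peak. The boundary-layer estimate
`boundaryLayerGradient()` returns `0.15` (mm⁻¹), the humidity gradient a
termite experiences over the 2 mm diffusive layer at 30% humidity drop.

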