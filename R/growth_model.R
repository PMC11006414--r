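## Curvature-driven phase-field growth on a voxelized scene.
##
## The order parameter f is 1 in the nest wall (solid) and 0 in air. The
## growth law, in lattice units (grid spacing = 1 voxel),
##
##   df/dt = f(1-f) * (d*K + lap K),   K = -lap f,
##
## combines a growth term proportional to the interface mean curvature
## (convex solid features accrete) with a curvature-diffusion term that
## relaxes curvature variation and cuts off growth below the pellet scale.
## Small-slope analysis gives the interface velocity v = d*kappa - lap_s
## kappa, i.e. a growth rate sigma(k) = d k^2 - k^4 with fastest-growing
## wavelength 2*pi*sqrt(2/d) voxels. Initially solid voxels above the frozen
## threshold never change (dried structures are not re-worked).

#' Initialize the phase field from a solid mask
#'
#' Sets f = 1 inside the solid and 0 in the air, then unsharpens the
#' transition with a Gaussian filter. Voxels where the smoothed f exceeds
#' `frozenThreshold` are frozen for the whole run.
#'
#' @param mask a [SolidMask-class]; must contain both solid and air.
#' @param params a [GrowthParams-class].
#' @return A [PhaseField-class] at t = 0.
#' @export
initializeField <- function(mask, params = growthParams()) {
  stopifnot(is(mask, "SolidMask"), is(params, "GrowthParams"))
  v <- mask@values
  if (all(v) || !any(v)) stop("mask must contain both solid and air voxels")
  f <- as.numeric(v)
  sigmaVox <- params@smoothingSigma / mask@spacing
  if (sigmaVox > 0) f <- cpp_blur3d(f, dim(v), sigmaVox)
  f <- array(pmin(pmax(f, 0), 1), dim(v))
  frozen <- f > params@frozenThreshold
  new("PhaseField", values = f, frozen = frozen, spacing = mask@spacing,
      origin = mask@origin, time = 0)
}

#' Mean-curvature field of an order parameter
#'
#' Two discretizations of the interface mean curvature, both signed so that
#' convex solid (high-f) features are positive, in voxel^-1 units:
#' `"laplacian"` returns `-lap f`, the quantity the growth law uses (it
#' approximates curvature times `|grad f|` near the interface);
#' `"divergence"` returns the exact regularized `-div(grad f / |grad f|)`,
#' which equals 2/R on a solid sphere of radius R and 1/R on a cylinder.
#'
#' @param f 3D numeric array (the order parameter).
#' @param method "laplacian" or "divergence".
#' @param eps regularization of the gradient norm (divergence method).
#' @return 3D array of curvature values (voxel^-1).
#' @export
meanCurvature <- function(f, method = c("laplacian", "divergence"),
                          eps = 1e-6) {
  method <- match.arg(method)
  d <- dim(f)
  if (method == "laplacian")
    return(array(-cpp_lap3d(as.numeric(f), d), d))
  sh <- function(a, di, dj, dk) {
    idx <- function(n, dd) pmin(pmax(seq_len(n) + dd, 1), n)  # mirror-clamp
    a[idx(d[1], di), idx(d[2], dj), idx(d[3], dk)]
  }
  gx <- (sh(f, 1, 0, 0) - sh(f, -1, 0, 0)) / 2
  gy <- (sh(f, 0, 1, 0) - sh(f, 0, -1, 0)) / 2
  gz <- (sh(f, 0, 0, 1) - sh(f, 0, 0, -1)) / 2
  nrm <- sqrt(gx^2 + gy^2 + gz^2 + eps^2)
  nx <- gx / nrm; ny <- gy / nrm; nz <- gz / nrm
  div <- (sh(nx, 1, 0, 0) - sh(nx, -1, 0, 0)) / 2 +
         (sh(ny, 0, 1, 0) - sh(ny, 0, -1, 0)) / 2 +
         (sh(nz, 0, 0, 1) - sh(nz, 0, 0, -1)) / 2
  -div
}

#' Curvature field of a phase field
#'
#' @param pf a [PhaseField-class].
#' @param method passed to [meanCurvature()].
#' @param units "lattice" (voxel^-1) or "mm" (mm^-1).
#' @return 3D curvature array.
#' @export
curvatureField <- function(pf, method = c("laplacian", "divergence"),
                           units = c("lattice", "mm")) {
  units <- match.arg(units)
  K <- meanCurvature(pf@values, method)
  if (units == "mm") K <- K / pf@spacing
  K
}

#' Advance the phase field
#'
#' Explicit-Euler integration of the growth law for `nsteps` steps of
#' `params@dt`. Frozen voxels are pinned; the field is clipped to [0,1];
#' a NaN aborts with a diagnostic.
#'
#' @param pf a [PhaseField-class].
#' @param params a [GrowthParams-class].
#' @param nsteps number of steps (default 1).
#' @return The advanced [PhaseField-class].
#' @export
growthStep <- function(pf, params, nsteps = 1L) {
  stopifnot(is(pf, "PhaseField"), is(params, "GrowthParams"))
  validObject(params)
  if (nsteps == 0) return(pf)
  res <- cpp_growth_run(as.numeric(pf@values), as.logical(pf@frozen),
                        dim(pf@values), params@d, params@dt,
                        as.integer(nsteps))
  new("PhaseField", values = array(res$f, dim(pf@values)), frozen = pf@frozen,
      spacing = pf@spacing, origin = pf@origin,
      time = pf@time + nsteps * params@dt)
}

#' Run the growth model and collect snapshots
#'
#' Integrates from the field's current time to `params@tEnd`, returning the
#' field at each requested snapshot time (rounded to the nearest step).
#' Deterministic: identical inputs give bitwise-identical snapshots.
#'
#' @param pf0 the initial [PhaseField-class].
#' @param params a [GrowthParams-class].
#' @return Named list of [PhaseField-class] snapshots ("t=...").
#' @export
runGrowth <- function(pf0, params) {
  times <- sort(unique(pmin(params@snapshotTimes, params@tEnd)))
  stepsAt <- round(times / params@dt)
  out <- vector("list", length(times))
  names(out) <- sprintf("t=%g", times)
  pf <- pf0
  done <- 0
  for (s in seq_along(times)) {
    need <- stepsAt[s] - done
    if (need > 0) pf <- growthStep(pf, params, need)
    done <- stepsAt[s]
    out[[s]] <- pf
  }
  out
}

#' Voxels of added material
#'
#' Voxels that are solid (f >= 0.5, ties toward solid) in the final field but
#' not in the initial one.
#'
#' @param pf0,pfT initial and final [PhaseField-class] on the same grid.
#' @return Integer matrix of voxel indices (columns i, j, k); zero rows when
#'   nothing was added.
#' @export
depositionVoxels <- function(pf0, pfT) {
  if (!identical(dim(pf0@values), dim(pfT@values)) ||
      !isTRUE(all.equal(pf0@spacing, pfT@spacing)))
    stop("phase fields are on different grids")
  added <- (pfT@values >= 0.5) & (pf0@values < 0.5)
  which(added, arr.ind = TRUE)
}

#' Project added voxels to the original surface and profile them radially
#'
#' Reproduces the simulation-to-experiment comparison: added voxels near a
#' vertical cutting plane are mapped to their nearest voxel on the original
#' surface, and the horizontal radial positions of those surface voxels are
#' histogrammed, normalized by the histogram maximum.
#'
#' @param voxels index matrix from [depositionVoxels()].
#' @param pf0 the initial [PhaseField-class] (defines the original surface).
#' @param planeAxis "y" (default) or "x": the cut is the plane axis = value.
#' @param planeValue plane position in mm (default 0, through the cue line).
#' @param slabHalfWidth half-thickness of the selection slab in mm (default 1).
#' @param binWidth histogram bin width in mm (default 0.5).
#' @return A max-normalized [RadialProfile-class]. An empty selection gives a
#'   zero-length profile (flagged by its length).
#' @export
projectAndProfile <- function(voxels, pf0, planeAxis = c("y", "x"),
                              planeValue = 0, slabHalfWidth = 1,
                              binWidth = 0.5) {
  planeAxis <- match.arg(planeAxis)
  if (is.null(dim(voxels)) || nrow(voxels) == 0)
    stop("no added voxels to profile")
  sp <- pf0@spacing
  co <- cbind(pf0@origin[1] + (voxels[, 1] - 0.5) * sp,
              pf0@origin[2] + (voxels[, 2] - 0.5) * sp,
              pf0@origin[3] + (voxels[, 3] - 0.5) * sp)
  axcol <- if (planeAxis == "y") 2L else 1L
  keep <- abs(co[, axcol] - planeValue) <= slabHalfWidth
  if (!any(keep))
    return(new("RadialProfile", bins = numeric(0), values = numeric(0),
               normalization = "max"))
  co <- co[keep, , drop = FALSE]

  solid0 <- pf0@values >= 0.5
  surf <- solid0 & .surfaceAdjacentSolid(solid0)
  sidx <- which(surf, arr.ind = TRUE)
  sco <- cbind(pf0@origin[1] + (sidx[, 1] - 0.5) * sp,
               pf0@origin[2] + (sidx[, 2] - 0.5) * sp,
               pf0@origin[3] + (sidx[, 3] - 0.5) * sp)
  nn <- cpp_nearest_index(co, sco)
  r <- sqrt(sco[nn, 1]^2 + sco[nn, 2]^2)
  breaks <- seq(0, max(r) + binWidth, by = binWidth)
  hh <- hist(r, breaks = breaks, plot = FALSE)
  vals <- hh$counts / max(hh$counts)
  new("RadialProfile", bins = hh$mids, values = vals, normalization = "max")
}

## solid voxels face-adjacent to air
.surfaceAdjacentSolid <- function(solid) {
  d <- dim(solid)
  adj <- array(FALSE, d)
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    a <- .shift3(solid * 1, s[1], s[2], s[3])
    adj <- adj | (is.na(a) & FALSE) | (!is.na(a) & a == 0)
  }
  adj
}

#' Calibrate the pattern-scale parameter d
#'
#' Sweeps candidate values of `d` on a noisy flat interface and selects the
#' one whose dominant emergent wavelength (radial spectral peak of the
#' interface height after a fixed integration time) is closest to
#' `targetScale` mm. Candidates default to multiples of the linear-theory
#' value `2 * (2*pi*spacing/targetScale)^2`.
#'
#' @param spacing voxel size in mm.
#' @param targetScale target feature scale in mm (default 3, the cue
#'   thickness).
#' @param candidates candidate d values (lattice units).
#' @param domain lattice dimensions of the test slab (nx, ny, nz).
#' @param slabHeight flat-slab thickness in voxels.
#' @param noiseAmp interface noise amplitude in voxels.
#' @param ampFactor target log-amplification of the fastest mode: each
#'   candidate integrates to `t = ampFactor / (d^2/4)` (capped at `tMax`),
#'   long enough for the pattern to express but short of the coarsening
#'   regime.
#' @param tMax cap on the per-candidate integration time.
#' @param seed RNG seed for the interface noise.
#' @return list with the chosen `d`, the `table` of candidate wavelengths
#'   (mm), and the target.
#' @export
calibrateD <- function(spacing, targetScale = 3, candidates = NULL,
                       domain = c(84, 84, 24), slabHeight = 8,
                       noiseAmp = 0.2, ampFactor = 5, tMax = 200, seed = 1) {
  dTheory <- 2 * (2 * pi * spacing / targetScale)^2
  if (is.null(candidates)) candidates <- dTheory * c(0.5, 0.75, 1, 1.4, 2)
  set.seed(seed)
  nx <- domain[1]; ny <- domain[2]; nz <- domain[3]
  zeta <- slabHeight + matrix(rnorm(nx * ny, sd = noiseAmp), nx, ny)
  mask <- array(FALSE, c(nx, ny, nz))
  for (k in seq_len(nz)) mask[, , k] <- zeta > (k - 0.5)
  sm <- new("SolidMask", values = mask, spacing = spacing,
            origin = c(-nx / 2, -ny / 2, 0) * spacing)
  lambdas <- vapply(candidates, function(d) {
    ## integrate to amplify the fastest mode (rate d^2/4) by e^ampFactor over
    ## its initial amplitude, compensating the Gaussian-unsharpening damping
    ## exp(-k*^2 sigma^2 / 2) of that mode
    sigmaVox <- 1.5
    damp <- (d / 2) * sigmaVox^2 / 2
    tEnd <- min(tMax, (ampFactor + damp) / (d^2 / 4))
    p <- growthParams(d = d, tEnd = tEnd, smoothingSigma = sigmaVox * spacing)
    pf <- initializeField(sm, p)
    pfT <- growthStep(pf, p, nsteps = round(tEnd / p@dt))
    .dominantWavelength(interfaceHeight(pfT)) * spacing
  }, numeric(1))
  best <- which.min(abs(lambdas - targetScale))
  list(d = candidates[best], table = data.frame(d = candidates,
       wavelength_mm = lambdas), target = targetScale, theory = dTheory)
}

#' Interface height map of a phase field
#'
#' Per-column elevation (in voxels) of the topmost downward crossing of
#' f = 0.5, linearly interpolated; 0 for columns with no solid.
#'
#' @param pf a [PhaseField-class].
#' @return numeric matrix (nx x ny) of heights in voxel units.
#' @export
interfaceHeight <- function(pf) {
  f <- pf@values
  d <- dim(f)
  out <- matrix(0, d[1], d[2])
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    col <- f[i, j, ]
    below <- which(col >= 0.5)
    if (!length(below)) next
    k <- max(below)
    if (k == d[3]) { out[i, j] <- k; next }
    ## crossing between k and k+1
    out[i, j] <- (k - 0.5) + (col[k] - 0.5) / max(col[k] - col[k + 1], 1e-12)
  }
  out
}

## dominant wavelength (in grid units) of a 2D field via radially binned
## power spectrum, excluding the DC mode
.dominantWavelength <- function(z) {
  z <- z - mean(z)
  nx <- nrow(z); ny <- ncol(z)
  P <- Mod(fft(z))^2
  kx <- c(seq(0, floor(nx / 2)), seq(-(nx - floor(nx / 2) - 1), -1)) / nx
  ky <- c(seq(0, floor(ny / 2)), seq(-(ny - floor(ny / 2) - 1), -1)) / ny
  kk <- sqrt(outer(kx^2, ky^2, "+"))
  ## bin by |k| in steps of the fundamental
  kbin <- round(kk * nx)
  ok <- kbin > 0
  pw <- tapply(P[ok], kbin[ok], sum)
  kpk <- as.numeric(names(pw))[which.max(pw)] / nx
  1 / kpk
}
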