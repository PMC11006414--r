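#' @import methods
#' @importFrom stats median mad fft quantile chisq.test cor rnorm runif sd
#'   approx rpois
#' @importFrom graphics hist
#' @importFrom utils read.csv write.csv write.table head tail
#' @useDynLib nestflux, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Parametric arena scene
#'
#' Describes the experimental arena: a humid clay disk at the center of a
#' Petri dish, optionally decorated with a topographic cue (two pillars or a
#' wall) and carrying an annular band of loose pellets. All lengths are in
#' millimetres; the coordinate origin is at the arena center, x-y in the
#' Petri plane, z up.
#'
#' @slot arenaRadius Petri dish radius (mm).
#' @slot diskRadius clay disk radius (mm).
#' @slot diskThickness clay disk thickness (mm).
#' @slot cueType one of "pillars", "wall", "none".
#' @slot pillarHeight,pillarSpacing,pillarDiameter pillar geometry (mm);
#'   spacing is center-to-center along the x axis.
#' @slot wallHeight,wallLength,wallThickness wall geometry (mm); the wall
#'   long axis lies along x.
#' @slot pelletBand inner and outer radius (mm) of the pellet band.
#' @slot pelletDiameter pellet diameter (mm).
#' @slot edgeSmoothing width (mm) of the smoothing ramp applied to disk and
#'   cue edges.
#' @export
setClass("SceneSpec", representation(
  arenaRadius = "numeric", diskRadius = "numeric", diskThickness = "numeric",
  cueType = "character",
  pillarHeight = "numeric", pillarSpacing = "numeric", pillarDiameter = "numeric",
  wallHeight = "numeric", wallLength = "numeric", wallThickness = "numeric",
  pelletBand = "numeric", pelletDiameter = "numeric", edgeSmoothing = "numeric"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  lens <- c(object@arenaRadius, object@diskRadius, object@diskThickness,
            object@pillarHeight, object@pillarSpacing, object@pillarDiameter,
            object@wallHeight, object@wallLength, object@wallThickness,
            object@pelletDiameter)
  if (any(!is.finite(lens)) || any(lens <= 0))
    msg <- c(msg, "all lengths must be positive and finite")
  if (!object@cueType %in% c("pillars", "wall", "none"))
    msg <- c(msg, "cueType must be 'pillars', 'wall' or 'none'")
  if (object@diskRadius >= object@arenaRadius)
    msg <- c(msg, "diskRadius must be smaller than arenaRadius")
  if (length(object@pelletBand) != 2L || object@pelletBand[1] >= object@pelletBand[2])
    msg <- c(msg, "pelletBand must be (inner, outer) with inner < outer")
  else if (object@pelletBand[2] > object@diskRadius)
    msg <- c(msg, "pellet band must lie inside the clay disk")
  if (object@edgeSmoothing < 0) msg <- c(msg, "edgeSmoothing must be >= 0")
  ## cue footprint must fit inside the disk
  foot <- switch(object@cueType,
    pillars = object@pillarSpacing / 2 + object@pillarDiameter / 2,
    wall = sqrt((object@wallLength / 2)^2 + (object@wallThickness / 2)^2),
    none = 0)
  if (foot > object@diskRadius)
    msg <- c(msg, "cue footprint extends outside the clay disk")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneSpec
#'
#' Defaults reproduce the reference setup: a 50 mm clay disk in an 85 mm
#' Petri dish, pillars 6 mm high and 8 mm apart (or a wall 6 mm high, 12 mm
#' long), 3 mm thick cues, and a 10 mm wide pellet band halfway between the
#' disk center and its edge. The disk thickness is not a controlled quantity
#' in the reference setup; 1.5 mm corresponds to ~2.8 g of wet clay spread
#' over a 50 mm disk.
#'
#' @param cueType "pillars", "wall" or "none".
#' @param arenaRadius,diskRadius,diskThickness arena geometry (mm).
#' @param pillarHeight,pillarSpacing,pillarDiameter pillar cue geometry (mm).
#' @param wallHeight,wallLength,wallThickness wall cue geometry (mm).
#' @param pelletBand numeric length-2, inner/outer radius (mm) of pellet band.
#' @param pelletDiameter pellet size (mm).
#' @param edgeSmoothing smoothing ramp width (mm) at disk and cue edges.
#' @return A validated [SceneSpec-class] object.
#' @examples
#' sceneSpec("pillars")
#' @export
sceneSpec <- function(cueType = c("pillars", "wall", "none"),
                      arenaRadius = 42.5, diskRadius = 25, diskThickness = 1.5,
                      pillarHeight = 6, pillarSpacing = 8, pillarDiameter = 3,
                      wallHeight = 6, wallLength = 12, wallThickness = 3,
                      pelletBand = c(7.5, 17.5), pelletDiameter = 0.75,
                      edgeSmoothing = 1) {
  cueType <- match.arg(cueType)
  new("SceneSpec", arenaRadius = arenaRadius, diskRadius = diskRadius,
      diskThickness = diskThickness, cueType = cueType,
      pillarHeight = pillarHeight, pillarSpacing = pillarSpacing,
      pillarDiameter = pillarDiameter, wallHeight = wallHeight,
      wallLength = wallLength, wallThickness = wallThickness,
      pelletBand = pelletBand, pelletDiameter = pelletDiameter,
      edgeSmoothing = edgeSmoothing)
}

setMethod("show", "SceneSpec", function(object) {
  cat("SceneSpec:", object@cueType, "cue\n")
  cat("  arena R", object@arenaRadius, "mm | disk R", object@diskRadius,
      "mm x", object@diskThickness, "mm\n")
  if (object@cueType == "pillars")
    cat("  pillars:", object@pillarHeight, "mm high,", object@pillarSpacing,
        "mm apart, d =", object@pillarDiameter, "mm\n")
  if (object@cueType == "wall")
    cat("  wall:", object@wallHeight, "mm high,", object@wallLength,
        "mm long,", object@wallThickness, "mm thick\n")
  cat("  pellet band [", object@pelletBand[1], ",", object@pelletBand[2],
      "] mm, pellets", object@pelletDiameter, "mm\n")
})

#' Regular-grid containers
#'
#' `HeightMap` stores a single-valued elevation field over a regular x-y grid
#' (mm); `SolidMask` a 3D boolean occupancy grid; `PhaseField` the growth
#' model's order parameter together with its frozen set; `HumidityField` a
#' steady-state relative-humidity field on air voxels; `GradientMap` the
#' humidity-gradient magnitude (fraction/mm). All grids are cell-centered:
#' voxel (i,j,k) has center `origin + (i-1/2, j-1/2, k-1/2) * spacing`.
#'
#' @slot values numeric matrix (HeightMap) or 3D array (fields).
#' @slot spacing grid spacing in mm.
#' @slot origin physical position of the grid corner (mm).
#' @name grids
NULL

#' @rdname grids
#' @export
setClass("HeightMap", representation(
  values = "matrix", spacing = "numeric", origin = "numeric"))

setValidity("HeightMap", function(object) {
  if (length(object@spacing) != 1L || object@spacing <= 0)
    return("spacing must be a single positive number")
  if (length(object@origin) != 2L) return("origin must be length 2 (x, y)")
  if (any(object@values < -1e-9, na.rm = TRUE))
    return("elevations must be non-negative")
  TRUE
})

#' @rdname grids
#' @export
setClass("SolidMask", representation(
  values = "array", spacing = "numeric", origin = "numeric"))

setValidity("SolidMask", function(object) {
  if (!is.logical(object@values) || length(dim(object@values)) != 3L)
    return("values must be a 3D logical array")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    return("spacing must be a single positive number")
  if (length(object@origin) != 3L) return("origin must be length 3 (x, y, z)")
  TRUE
})

#' @rdname grids
#' @export
setClass("PhaseField", representation(
  values = "array", frozen = "array", spacing = "numeric", origin = "numeric",
  time = "numeric"))

setValidity("PhaseField", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3D array")
  if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
    return("order parameter must lie in [0, 1]")
  if (!identical(dim(object@frozen), dim(v)))
    return("frozen mask must match field dimensions")
  TRUE
})

#' @rdname grids
#' @export
setClass("HumidityField", representation(
  h = "array", solid = "array", spacing = "numeric", origin = "numeric",
  hSurface = "numeric", hTop = "numeric", residual = "numeric",
  iterations = "numeric"))

#' @rdname grids
#' @export
setClass("GradientMap", representation(
  values = "array", solid = "array", spacing = "numeric", origin = "numeric"))

#' Growth-model parameters
#'
#' Parameters of the curvature-driven phase-field growth law. The model works
#' in lattice units (grid spacing = 1); `d` selects the length scale of the
#' expressed pattern (the fastest-growing wavelength is `2*pi*sqrt(2/d)`
#' voxels). The explicit-Euler step is bounded by the biharmonic-dominated
#' stability limit `dt <= 1 / (8 * (d + 4))` (lattice units), enforced at
#' construction.
#'
#' @slot d curvature-response parameter (lattice units).
#' @slot dt time step (dimensionless).
#' @slot tEnd end time (dimensionless).
#' @slot snapshotTimes times at which to keep snapshots.
#' @slot smoothingSigma Gaussian unsharpening of the initial interface (mm).
#' @slot frozenThreshold voxels with initial f above this never change.
#' @export
setClass("GrowthParams", representation(
  d = "numeric", dt = "numeric", tEnd = "numeric", snapshotTimes = "numeric",
  smoothingSigma = "numeric", frozenThreshold = "numeric"))

setValidity("GrowthParams", function(object) {
  msg <- character()
  if (object@d <= 0) msg <- c(msg, "d must be positive")
  bound <- 1 / (8 * (object@d + 4))
  if (object@dt <= 0 || object@dt > bound)
    msg <- c(msg, sprintf("dt must be in (0, %.3g] (explicit stability bound)", bound))
  if (object@frozenThreshold <= 0.5 || object@frozenThreshold >= 1)
    msg <- c(msg, "frozenThreshold must be in (0.5, 1)")
  if (object@tEnd < 0) msg <- c(msg, "tEnd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct GrowthParams
#'
#' @param d curvature-response parameter (lattice units); see [calibrateD()].
#' @param dt time step; defaults to 0.9 of the stability bound.
#' @param tEnd dimensionless end time (default 9).
#' @param snapshotTimes snapshot times (default `c(0, tEnd)`).
#' @param smoothingSigma initial-interface Gaussian sigma in mm (default 0.3).
#' @param frozenThreshold frozen-set level (default 0.85).
#' @return A [GrowthParams-class] object.
#' @export
growthParams <- function(d = 0.35, dt = NULL, tEnd = 9, snapshotTimes = NULL,
                         smoothingSigma = 0.3, frozenThreshold = 0.85) {
  if (is.null(dt)) dt <- 0.9 / (8 * (d + 4))
  if (is.null(snapshotTimes)) snapshotTimes <- unique(c(0, tEnd))
  new("GrowthParams", d = d, dt = dt, tEnd = tEnd,
      snapshotTimes = sort(snapshotTimes), smoothingSigma = smoothingSigma,
      frozenThreshold = frozenThreshold)
}

#' Diffusive boundary-layer parameters
#'
#' @slot delta boundary-layer thickness (mm).
#' @slot deltaH relative-humidity drop across the layer (%).
#' @export
setClass("BoundaryLayerParams", representation(
  delta = "numeric", deltaH = "numeric"))

setValidity("BoundaryLayerParams", function(object) {
  if (object@delta <= 0) return("delta must be positive")
  if (object@deltaH < 0) return("deltaH must be non-negative")
  TRUE
})

#' @param delta boundary-layer thickness in mm (default 2).
#' @param deltaH humidity drop in percent (default 30).
#' @rdname BoundaryLayerParams-class
#' @export
boundaryLayerParams <- function(delta = 2, deltaH = 30) {
  new("BoundaryLayerParams", delta = delta, deltaH = deltaH)
}

#' Radial profile
#'
#' A 1D profile over radius (or signed position along a cut), with its
#' normalization convention recorded: "sum" profiles integrate to 1, "max"
#' profiles peak at 1, "none" is raw.
#'
#' @slot bins bin centers (mm).
#' @slot values profile values.
#' @slot normalization "sum", "max" or "none".
#' @export
setClass("RadialProfile", representation(
  bins = "numeric", values = "numeric", normalization = "character"))

setValidity("RadialProfile", function(object) {
  if (length(object@bins) != length(object@values))
    return("bins and values must have equal length")
  if (!object@normalization %in% c("sum", "max", "none"))
    return("normalization must be 'sum', 'max' or 'none'")
  if (object@normalization == "sum" && length(object@values) &&
      abs(sum(object@values) - 1) > 1e-6)
    return("sum-normalized profile must sum to 1")
  if (object@normalization == "max" && length(object@values) &&
      abs(max(object@values) - 1) > 1e-6)
    return("max-normalized profile must peak at 1")
  TRUE
})

setMethod("show", "RadialProfile", function(object) {
  cat(sprintf("RadialProfile: %d bins [%.2f, %.2f] mm, %s-normalized\n",
              length(object@bins), min(object@bins), max(object@bins),
              object@normalization))
  if (length(object@values))
    cat(sprintf("  peak %.3g at R = %.2f mm\n", max(object@values),
                object@bins[which.max(object@values)]))
})

#' Peak location of a radial profile
#'
#' Argmax after smoothing with a centered moving average.
#'
#' @param profile a [RadialProfile-class].
#' @param smooth odd window length in bins (default 3).
#' @return radius (mm) of the smoothed maximum.
#' @export
profilePeak <- function(profile, smooth = 3) {
  v <- profile@values
  if (!length(v)) stop("empty profile")
  if (smooth > 1 && length(v) >= smooth) {
    k <- rep(1 / smooth, smooth)
    v <- as.numeric(stats::filter(v, k, sides = 2))
    v[is.na(v)] <- profile@values[is.na(v)]
  }
  profile@bins[which.max(v)]
}

## ---- shared accessors ----

#' Grid accessors
#'
#' `spacing()` returns the grid spacing in mm, `gridOrigin()` the physical
#' position of the grid corner, and `fieldValues()` the underlying matrix or
#' array.
#'
#' @param x a grid container.
#' @return numeric spacing / origin, or the value array.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname spacing
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname spacing
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

for (cl in c("HeightMap", "SolidMask", "PhaseField", "GradientMap")) {
  setMethod("spacing", cl, function(x) x@spacing)
  setMethod("gridOrigin", cl, function(x) x@origin)
  setMethod("fieldValues", cl, function(x) x@values)
}
setMethod("spacing", "HumidityField", function(x) x@spacing)
setMethod("gridOrigin", "HumidityField", function(x) x@origin)
setMethod("fieldValues", "HumidityField", function(x) x@h)

setMethod("show", "SolidMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("SolidMask %dx%dx%d @ %.3g mm (%d solid voxels, %.1f%%)\n",
              d[1], d[2], d[3], object@spacing, sum(object@values),
              100 * mean(object@values)))
})

setMethod("show", "PhaseField", function(object) {
  d <- dim(object@values)
  cat(sprintf("PhaseField %dx%dx%d @ %.3g mm, t = %.3g (%d frozen voxels)\n",
              d[1], d[2], d[3], object@spacing, object@time,
              sum(object@frozen)))
})

setMethod("show", "HumidityField", function(object) {
  d <- dim(object@h)
  cat(sprintf(paste0("HumidityField %dx%dx%d @ %.3g mm | h in [%.1f, %.1f]%%",
                     " | surface %.0f%%, top %.0f%% | residual %.2g (%d it)\n"),
              d[1], d[2], d[3], object@spacing,
              min(object@h, na.rm = TRUE), max(object@h, na.rm = TRUE),
              object@hSurface, object@hTop, object@residual,
              as.integer(object@iterations)))
})

## ---- shared internal helpers ----

## cell-center coordinates along one axis
.axisCenters <- function(n, spacing, origin) origin + (seq_len(n) - 0.5) * spacing

## coordinates of every cell center of a 2D grid, as two matrices
.gridXY <- function(nx, ny, spacing, origin) {
  list(x = matrix(.axisCenters(nx, spacing, origin[1]), nx, ny),
       y = matrix(.axisCenters(ny, spacing, origin[2]), nx, ny, byrow = TRUE))
}

## smooth ramp: 1 for u >= 1, 0 for u <= 0, cosine in between
.ramp <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  0.5 - 0.5 * cos(pi * u)
}
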