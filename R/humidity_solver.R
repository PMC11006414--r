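## Steady-state diffusive humidity over a voxelized scene: 7-point Laplace
## solve (conjugate gradients, matrix-free in C++), gradient-magnitude maps,
## per-surface-voxel evaporation flux, and the curvature-flux diagnostics.

#' Solve the steady-state humidity field over a scene
#'
#' Solves the Laplace equation on the air voxels of the domain with Dirichlet
#' `hSurface` on every air face adjacent to wet solid (the scanned setup is
#' the bottom boundary), Dirichlet `hTop` at the top plate, and zero-flux
#' lateral walls. Relative humidity is used as a proxy for absolute humidity
#' (constant temperature).
#'
#' @param mask a [SolidMask-class]; usually [cropToCube()] output so the
#'   domain is the standard 18 mm cube.
#' @param domainHeight vertical domain extent in mm (default 18); the mask is
#'   padded with air up to this height if needed.
#' @param hSurface relative humidity (%) at the wet solid surface (default 100).
#' @param hTop relative humidity (%) at the top plate (default 70).
#' @param wet logical array matching the mask (TRUE = evaporating surface);
#'   default: all solid is wet.
#' @param bottomWet treat the bare floor (z = 0 faces not covered by solid)
#'   as wet (default TRUE); set FALSE for a dry Petri floor.
#' @param cold optional logical array: a far-field region held at `hTop`
#'   (e.g. an outer shell around an isolated droplet); excluded from the
#'   unknowns.
#' @param tol relative CG residual tolerance (default 1e-8).
#' @param maxit CG iteration cap.
#' @return A [HumidityField-class] (`NA` inside solid).
#' @examples
#' m <- new("SolidMask", values = array(FALSE, c(8, 8, 12)),
#'          spacing = 1.5, origin = c(-6, -6, 0))
#' hf <- solveLaplace(m, domainHeight = 18)
#' @export
solveLaplace <- function(mask, domainHeight = 18, hSurface = 100, hTop = 70,
                         wet = NULL, bottomWet = TRUE, cold = NULL,
                         tol = 1e-8, maxit = 20000L) {
  stopifnot(is(mask, "SolidMask"))
  sp <- mask@spacing
  v <- mask@values
  nz <- round(domainHeight / sp)
  d <- dim(v)
  if (nz > d[3]) {
    pad <- array(FALSE, c(d[1], d[2], nz - d[3]))
    v <- array(c(v, pad), c(d[1], d[2], nz))
    if (!is.null(wet)) wet <- array(c(wet, pad), c(d[1], d[2], nz))
    if (!is.null(cold)) cold <- array(c(cold, pad), c(d[1], d[2], nz))
  } else if (nz < d[3]) {
    stop("mask is taller than the requested domain height")
  }
  if (is.null(wet)) wet <- v
  if (is.null(cold)) cold <- array(FALSE, dim(v))
  stopifnot(identical(dim(wet), dim(v)), identical(dim(cold), dim(v)))
  if (all(v | cold)) stop("no air voxels: domain entirely solid")
  ## the air must connect the surface to the top plate (or far-field region)
  if (!any(cold) && !any(!v[, , nz]))
    stop("top layer is solid; air cannot reach the top plate")
  reach <- array(cpp_flood_air(as.logical(v), as.logical(cold), dim(v)), dim(v))
  if (any(!v & !cold & !reach))
    stop("disconnected air region: ", sum(!v & !cold & !reach),
         " air voxels cannot reach the top plate")

  sol <- cpp_cg_laplace(as.logical(v), as.logical(wet & v), as.logical(cold),
                        dim(v), hSurface, hTop, bottomWet, tol,
                        as.integer(maxit))
  if (!sol$converged)
    warning(sprintf("CG did not reach tol: relative residual %.3g after %d iterations",
                    sol$residual, sol$iterations))
  h <- array(sol$h, dim(v))
  new("HumidityField", h = h, solid = v, spacing = sp,
      origin = mask@origin, hSurface = hSurface, hTop = hTop,
      residual = sol$residual, iterations = as.numeric(sol$iterations))
}

## shifted-neighbor array with NA padding
.shift3 <- function(a, di, dj, dk) {
  d <- dim(a)
  out <- array(NA_real_, d)
  ix <- seq_len(d[1]); jx <- seq_len(d[2]); kx <- seq_len(d[3])
  si <- ix + di; sj <- jx + dj; sk <- kx + dk
  ok_i <- si >= 1 & si <= d[1]; ok_j <- sj >= 1 & sj <= d[2]; ok_k <- sk >= 1 & sk <= d[3]
  out[ix[ok_i], jx[ok_j], kx[ok_k]] <- a[si[ok_i], sj[ok_j], sk[ok_k]]
  out
}

#' Humidity-gradient magnitude map
#'
#' Computes `|grad h|` per air voxel on the relative-humidity-fraction scale
#' (units 1/mm: a 30% drop over 2 mm is 0.15/mm). Centered differences in the
#' air interior; faces adjacent to solid use the surface Dirichlet value, and
#' domain faces use one-sided differences (bottom/top use the plate values).
#'
#' @param hf a [HumidityField-class].
#' @param bottomWet as in [solveLaplace()].
#' @return A [GradientMap-class] (`NA` inside solid).
#' @export
gradientMap <- function(hf, bottomWet = TRUE) {
  h <- hf@h
  solid <- hf@solid
  sp <- hf@spacing
  d <- dim(h)
  ## neighbor value and its distance from the voxel center: air neighbors at
  ## one spacing; Dirichlet values (solid surface, bottom, top plate) on the
  ## voxel face at half a spacing; NA = zero-flux (lateral walls, dry floor)
  nbr <- function(di, dj, dk) {
    a <- .shift3(h, di, dj, dk)
    dist <- array(sp, d)
    s <- .shift3(solid * 1, di, dj, dk)
    onsolid <- !is.na(s) & s == 1
    a[onsolid] <- hf@hSurface
    dist[onsolid] <- sp / 2
    if (dk == -1 && bottomWet) { a[, , 1] <- hf@hSurface; dist[, , 1] <- sp / 2 }
    if (dk == 1) { a[, , d[3]] <- hf@hTop; dist[, , d[3]] <- sp / 2 }
    dist[is.na(a)] <- NA_real_
    list(v = a, d = dist)
  }
  deriv <- function(plus, minus) {
    ctr <- (plus$v - minus$v) / (plus$d + minus$d)
    fwd <- (plus$v - h) / plus$d
    bwd <- (h - minus$v) / minus$d
    out <- ctr
    out[is.na(ctr)] <- fwd[is.na(ctr)]
    out[is.na(out)] <- bwd[is.na(out)]
    out[is.na(out)] <- 0
    out
  }
  gx <- deriv(nbr(1, 0, 0), nbr(-1, 0, 0))
  gy <- deriv(nbr(0, 1, 0), nbr(0, -1, 0))
  gz <- deriv(nbr(0, 0, 1), nbr(0, 0, -1))
  g <- sqrt(gx^2 + gy^2 + gz^2) / 100  # percent/mm -> fraction/mm
  g[solid] <- NA_real_
  new("GradientMap", values = g, solid = solid, spacing = sp, origin = hf@origin)
}

#' Per-surface-voxel evaporation flux
#'
#' Outward normal derivative of humidity at each wet solid surface voxel, up
#' to the constant diffusivity factor: the mean over exposed faces of the
#' face gradient `(hSurface - h_air) / (spacing/2)`, on the fraction/mm
#' scale. Also returns the per-face sum (used for flux conservation checks).
#'
#' @param hf a [HumidityField-class].
#' @return data.frame with voxel indices `i, j, k`, coordinates `x, y, z`
#'   (mm), number of exposed faces `nfaces`, mean flux `flux` (1/mm) and
#'   total face flux `fluxSum`.
#' @export
surfaceFlux <- function(hf) {
  h <- hf@h
  solid <- hf@solid
  sp <- hf@spacing
  d <- dim(h)
  ## air neighbor values seen from each solid voxel
  acc <- array(0, d); cnt <- array(0L, d)
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    a <- .shift3(h, s[1], s[2], s[3])
    open <- solid & !is.na(a)
    acc[open] <- acc[open] + (hf@hSurface - a[open])
    cnt[open] <- cnt[open] + 1L
  }
  surf <- which(solid & cnt > 0, arr.ind = TRUE)
  if (!nrow(surf)) stop("mask has no exposed surface voxels")
  ix <- surf[, 1]; jx <- surf[, 2]; kx <- surf[, 3]
  lin <- ix + d[1] * ((jx - 1) + d[2] * (kx - 1))
  data.frame(
    i = ix, j = jx, k = kx,
    x = hf@origin[1] + (ix - 0.5) * sp,
    y = hf@origin[2] + (jx - 0.5) * sp,
    z = hf@origin[3] + (kx - 0.5) * sp,
    nfaces = cnt[lin],
    flux = (acc[lin] / cnt[lin]) / (sp / 2) / 100,
    fluxSum = acc[lin] / (sp / 2) / 100)
}

#' Total flux balance between solid surface and top plate
#'
#' Under zero-flux lateral walls, the total evaporative flux leaving the wet
#' surface must pass through the top plate. Both totals use the one-sided face
#' differences of the discrete operator, so agreement checks solver
#' consistency.
#'
#' @param hf a [HumidityField-class].
#' @param bottomWet as in [solveLaplace()].
#' @return list with `surfaceTotal`, `topTotal` (fraction * mm^2 / mm) and
#'   their relative difference `relDiff`.
#' @export
fluxBalance <- function(hf, bottomWet = TRUE) {
  sp <- hf@spacing
  d <- dim(hf@h)
  surfaceTotal <- if (any(hf@solid)) sum(surfaceFlux(hf)$fluxSum) * sp^2 else 0
  ## add bare-floor contribution if the bottom plate is wet
  if (bottomWet) {
    bot <- hf@h[, , 1]
    openFloor <- !hf@solid[, , 1] & !is.na(bot)
    surfaceTotal <- surfaceTotal +
      sum((hf@hSurface - bot[openFloor]) / (sp / 2)) * sp^2 / 100
  }
  top <- hf@h[, , d[3]]
  openTop <- !hf@solid[, , d[3]]
  topTotal <- sum((top[openTop] - hf@hTop) / (sp / 2)) * sp^2 / 100
  list(surfaceTotal = surfaceTotal, topTotal = topTotal,
       relDiff = abs(surfaceTotal - topTotal) / max(abs(topTotal), 1e-12))
}

#' Gradient amplification at a cue tip
#'
#' Ratio of the maximum gradient magnitude over a tip region to the median
#' gradient over a flat reference region, the statistic used to quantify how
#' much topographic cues concentrate evaporation.
#'
#' @param gm a [GradientMap-class].
#' @param tipRegion,referenceRegion logical arrays matching the grid (air
#'   voxels to include); see [tipRegion()] and [flatReferenceRegion()].
#' @return the amplification ratio (fold).
#' @export
amplification <- function(gm, tipRegion, referenceRegion) {
  v <- gm@values
  if (!any(tipRegion, na.rm = TRUE) || !any(referenceRegion, na.rm = TRUE))
    stop("tip and reference regions must be nonempty")
  if (any(tipRegion & referenceRegion, na.rm = TRUE))
    stop("tip and reference regions must be disjoint")
  tip <- max(v[tipRegion], na.rm = TRUE)
  ref <- median(v[referenceRegion], na.rm = TRUE)
  tip / ref
}

## logical array of air voxels face-adjacent to solid
.surfaceAdjacentAir <- function(solid) {
  d <- dim(solid)
  adj <- array(FALSE, d)
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    a <- .shift3(solid * 1, s[1], s[2], s[3])
    adj <- adj | (!is.na(a) & a == 1)
  }
  adj & !solid
}

#' Tip region for amplification measurements
#'
#' Air voxels adjacent to the solid surface within `radius` mm (3D distance)
#' of the highest solid surface point.
#'
#' @param mask a [SolidMask-class] (the solve domain).
#' @param radius capture radius in mm (default 2).
#' @return logical array over the domain grid.
#' @export
tipRegion <- function(mask, radius = 2) {
  solid <- mask@values
  sp <- mask@spacing
  adj <- .surfaceAdjacentAir(solid)
  top <- which(solid, arr.ind = TRUE)
  top <- top[top[, 3] == max(top[, 3]), , drop = FALSE]
  idx <- which(adj, arr.ind = TRUE)
  ## distance from each surface-adjacent air voxel to the highest solid
  ## layer (the cue top), in mm
  pre <- abs(idx[, 3] - max(top[, 3])) * sp <= radius + sp  # cheap z cut
  keep <- logical(nrow(idx))
  if (any(pre)) {
    nn <- cpp_nearest_index(cbind(idx[pre, 1], idx[pre, 2], idx[pre, 3]) * sp,
                            cbind(top[, 1], top[, 2], top[, 3]) * sp)
    dd <- sqrt(rowSums((idx[pre, , drop = FALSE] * sp -
                          top[nn, , drop = FALSE] * sp)^2))
    keep[pre] <- dd <= radius
  }
  out <- array(FALSE, dim(solid))
  out[idx[keep, , drop = FALSE]] <- TRUE
  out
}

#' Flat-disk reference region
#'
#' Surface-adjacent air voxels whose horizontal radius from the arena center
#' lies in `[rmin, rmax]`, clipped away from the lateral domain walls.
#'
#' @param mask a [SolidMask-class].
#' @param rmin,rmax radial range in mm (defaults 8 and 15).
#' @param wallClear clearance from lateral domain walls in mm (default 0.5).
#' @return logical array over the domain grid.
#' @export
flatReferenceRegion <- function(mask, rmin = 8, rmax = 15, wallClear = 0.5) {
  solid <- mask@values
  sp <- mask@spacing
  d <- dim(solid)
  adj <- .surfaceAdjacentAir(solid)
  idx <- which(adj, arr.ind = TRUE)
  x <- mask@origin[1] + (idx[, 1] - 0.5) * sp
  y <- mask@origin[2] + (idx[, 2] - 0.5) * sp
  r <- sqrt(x^2 + y^2)
  xmax <- mask@origin[1] + d[1] * sp
  ymax <- mask@origin[2] + d[2] * sp
  keep <- r >= rmin & r <= rmax &
    x > mask@origin[1] + wallClear & x < xmax - wallClear &
    y > mask@origin[2] + wallClear & y < ymax - wallClear
  out <- array(FALSE, dim(solid))
  out[idx[keep, , drop = FALSE]] <- TRUE
  out
}

#' Boundary-layer humidity gradient
#'
#' The order-of-magnitude gradient `deltaH / delta` across the diffusive
#' boundary layer, on the fraction/mm scale: with the default 30% drop over
#' 2 mm this is 0.15 /mm.
#'
#' @param p a [BoundaryLayerParams-class] (default: delta 2 mm, deltaH 30%).
#' @return gradient in 1/mm.
#' @examples
#' boundaryLayerGradient()  # 0.15
#' @export
boundaryLayerGradient <- function(p = boundaryLayerParams()) {
  stopifnot(is(p, "BoundaryLayerParams"))
  validObject(p)
  (p@deltaH / 100) / p@delta
}

#' Rank correlation between surface flux and local curvature
#'
#' Correlates the per-surface-voxel evaporation flux with the local mean
#' curvature of the substrate (exact-divergence operator on the smoothed
#' solid indicator; positive over convex solid).
#'
#' @param flux data.frame from [surfaceFlux()].
#' @param mask the [SolidMask-class] the field was solved on.
#' @param sigma smoothing of the indicator in voxels (default 2).
#' @return list with `rho` (Spearman) and `n`; `rho` is `NA` (flagged) when
#'   either quantity is degenerate (constant).
#' @export
fluxCurvatureCorrelation <- function(flux, mask, sigma = 2) {
  if (nrow(flux) < 100)
    stop("need at least 100 surface voxels for a meaningful correlation")
  f <- cpp_blur3d(as.numeric(mask@values), dim(mask@values), sigma)
  f <- array(f, dim(mask@values))
  K <- meanCurvature(f, method = "divergence")
  d <- dim(mask@values)
  lin <- flux$i + d[1] * ((flux$j - 1) + d[2] * (flux$k - 1))
  kv <- K[lin]
  ok <- is.finite(kv) & is.finite(flux$flux)
  if (sd(kv[ok]) < 1e-12 || sd(flux$flux[ok]) < 1e-12)
    return(list(rho = NA_real_, n = sum(ok), degenerate = TRUE))
  list(rho = cor(kv[ok], flux$flux[ok], method = "spearman"), n = sum(ok),
       degenerate = FALSE)
}
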