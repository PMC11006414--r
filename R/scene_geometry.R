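## Scene geometry: parametric arena -> height map -> voxel occupancy, plus a
## reader for surface-scan meshes (ASCII STL/OBJ/PLY) voxelized by z-ray
## parity so the result is independent of face orientation.

#' Build the elevation map of a scene
#'
#' Rasterizes a [SceneSpec-class] onto a regular x-y grid: elevation equals
#' `diskThickness` over the clay disk, `diskThickness + cue height` over cue
#' footprints, and 0 outside the disk (the Petri floor datum). Edges are
#' smoothed with a cosine ramp of width `edgeSmoothing` that stays inside
#' each footprint, so the elevation is exactly zero outside the disk.
#'
#' @param spec a [SceneSpec-class].
#' @param spacing grid spacing in mm; must not exceed the pellet diameter.
#' @param extent half-width of the grid in mm (default `arenaRadius`).
#' @return A [HeightMap-class].
#' @examples
#' hm <- buildHeightMap(sceneSpec("none"), spacing = 0.5)
#' @export
buildHeightMap <- function(spec, spacing, extent = spec@arenaRadius) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  if (spacing > spec@pelletDiameter)
    stop("spacing must not exceed the pellet diameter (",
         spec@pelletDiameter, " mm)")
  n <- max(2L, ceiling(2 * extent / spacing))
  origin <- c(-n * spacing / 2, -n * spacing / 2)
  g <- .gridXY(n, n, spacing, origin)
  r <- sqrt(g$x^2 + g$y^2)
  w <- max(spec@edgeSmoothing, 1e-9)

  ## disk: full thickness for r <= R - w, zero at r >= R
  elev <- spec@diskThickness * .ramp((spec@diskRadius - r) / w)

  cue <- matrix(0, n, n)
  if (spec@cueType == "pillars") {
    pr <- spec@pillarDiameter / 2
    wc <- min(w, pr)  # ramp cannot exceed the footprint radius
    for (xc in c(-1, 1) * spec@pillarSpacing / 2) {
      rho <- sqrt((g$x - xc)^2 + g$y^2)
      cue <- cue + spec@pillarHeight * .ramp((pr - rho) / wc)
    }
  } else if (spec@cueType == "wall") {
    hx <- spec@wallLength / 2
    hy <- spec@wallThickness / 2
    wc <- min(w, hy)
    ## distance inside the rectangle footprint (negative outside)
    din <- pmin(hx - abs(g$x), hy - abs(g$y))
    cue <- spec@wallHeight * .ramp(din / wc)
  }
  new("HeightMap", values = elev + cue, spacing = spacing, origin = origin)
}

#' Voxelize a height map
#'
#' A voxel is solid iff its center lies below the elevation surface of its
#' column.
#'
#' @param hm a [HeightMap-class].
#' @param dz vertical voxel size in mm (defaults to the lateral spacing).
#' @param zmax domain height in mm (default: just covers the surface).
#' @return A [SolidMask-class] sharing the height map's lateral grid.
#' @export
voxelize <- function(hm, dz = spacing(hm), zmax = NULL) {
  stopifnot(is(hm, "HeightMap"), dz > 0)
  top <- max(hm@values)
  if (is.null(zmax)) zmax <- top + dz
  nz <- max(1L, ceiling(zmax / dz))
  nx <- nrow(hm@values); ny <- ncol(hm@values)
  zc <- .axisCenters(nz, dz, 0)
  mask <- array(FALSE, c(nx, ny, nz))
  for (k in seq_len(nz)) mask[, , k] <- hm@values > zc[k]
  new("SolidMask", values = mask, spacing = hm@spacing,
      origin = c(hm@origin, 0))
}

#' Column-wise elevation of a solid mask
#'
#' Height of the top solid voxel face per column (0 for empty columns).
#' @param mask a [SolidMask-class].
#' @return numeric matrix of elevations (mm).
#' @export
maskElevation <- function(mask) {
  v <- mask@values
  nz <- dim(v)[3]
  ## highest solid layer index per column
  top <- apply(v, c(1, 2), function(col) {
    w <- which(col)
    if (length(w)) max(w) else 0L
  })
  top * mask@spacing
}

## ---- mesh I/O ----

## Parse an ASCII mesh file into list(vertices = Nx3, faces = Mx3).
## Supported: ASCII STL, OBJ (v/f records), ASCII PLY.
.readMesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl" || any(grepl("^\\s*solid", head(txt, 1)))) {
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    if (!length(vl)) stop("no vertices found; only ASCII STL is supported")
    nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                     function(p) as.numeric(p[2:4]), numeric(3)))
    if (nrow(nums) %% 3 != 0) stop("degenerate STL: vertex count not a multiple of 3")
    faces <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
    return(list(vertices = nums, faces = faces))
  }
  if (ext == "obj") {
    vl <- grep("^v\\s", txt, value = TRUE)
    fl <- grep("^f\\s", txt, value = TRUE)
    if (!length(vl) || !length(fl)) stop("degenerate OBJ: missing v/f records")
    verts <- t(vapply(strsplit(trimws(vl), "\\s+"),
                      function(p) as.numeric(p[2:4]), numeric(3)))
    faces <- t(vapply(strsplit(trimws(fl), "\\s+"), function(p) {
      ix <- as.integer(sub("/.*", "", p[-1]))
      if (length(ix) != 3) stop("only triangle faces are supported")
      ix
    }, integer(3)))
    return(list(vertices = verts, faces = faces))
  }
  if (ext == "ply") {
    if (!grepl("^ply", txt[1])) stop("not a PLY file")
    endh <- grep("^end_header", txt)[1]
    nv <- as.integer(sub(".*vertex\\s+", "", grep("element vertex", txt, value = TRUE)[1]))
    nf <- as.integer(sub(".*face\\s+", "", grep("element face", txt, value = TRUE)[1]))
    if (is.na(nv) || is.na(nf)) stop("degenerate PLY header")
    body <- txt[(endh + 1):length(txt)]
    verts <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                      function(p) as.numeric(p[1:3]), numeric(3)))
    faces <- t(vapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"), function(p) {
      if (as.integer(p[1]) != 3) stop("only triangle faces are supported")
      as.integer(p[2:4]) + 1L
    }, integer(3)))
    return(list(vertices = verts, faces = faces))
  }
  stop("unsupported mesh format: ", ext, " (use ASCII STL, OBJ or PLY)")
}

## each edge may be shared by at most two triangles
.checkManifold <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (any(table(key) > 2))
    stop("non-manifold mesh: an edge is shared by more than two faces")
  invisible(TRUE)
}

#' Load a surface-scan mesh and voxelize it
#'
#' Reads a triangulated surface mesh (ASCII STL, OBJ or PLY; mm units,
#' arena-centered coordinates) and produces a [SolidMask-class] using z-ray
#' parity: a voxel center is solid iff an upward vertical ray crosses the
#' mesh an odd number of times. The test is independent of face orientation,
#' and a surface that is open at the bottom is implicitly closed against the
#' floor plane z = 0.
#'
#' @param path mesh file.
#' @param spacing lateral voxel size (mm).
#' @param dz vertical voxel size (mm, default `spacing`).
#' @param extent grid half-width in mm (default from mesh bounds).
#' @return A [SolidMask-class].
#' @export
loadScanMesh <- function(path, spacing, dz = spacing, extent = NULL) {
  mesh <- .readMesh(path)
  .checkManifold(mesh)
  v <- mesh$vertices
  if (any(!is.finite(v))) stop("degenerate mesh: non-finite vertex")
  if (is.null(extent)) extent <- max(abs(v[, 1:2])) + spacing
  n <- max(2L, ceiling(2 * extent / spacing))
  origin <- c(-n * spacing / 2, -n * spacing / 2)
  zmax <- max(v[, 3]) + dz
  nz <- max(1L, ceiling(zmax / dz))
  xc <- .axisCenters(n, spacing, origin[1])
  yc <- .axisCenters(n, spacing, origin[2])
  zc <- .axisCenters(nz, dz, 0)
  ## jitter the ray positions (by incommensurate offsets) so no ray passes
  ## exactly through a mesh vertex or edge, which would break parity counting
  xq <- xc + spacing * 7.3e-5
  yq <- yc + spacing * 3.1e-5

  ## per-column sorted z-crossings of the mesh
  crossings <- vector("list", n * n)
  f <- mesh$faces
  for (t in seq_len(nrow(f))) {
    tri <- v[f[t, ], , drop = FALSE]
    xr <- range(tri[, 1]); yr <- range(tri[, 2])
    is <- which(xq >= xr[1] - spacing & xq <= xr[2] + spacing)
    js <- which(yq >= yr[1] - spacing & yq <= yr[2] + spacing)
    if (!length(is) || !length(js)) next
    d <- (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
         (tri[3, 1] - tri[1, 1]) * (tri[2, 2] - tri[1, 2])
    if (abs(d) < 1e-12) next  # vertical triangle: no z-crossing
    for (i in is) for (j in js) {
      px <- xq[i] - tri[1, 1]; py <- yq[j] - tri[1, 2]
      l2 <- (px * (tri[3, 2] - tri[1, 2]) - py * (tri[3, 1] - tri[1, 1])) / d
      l3 <- (py * (tri[2, 1] - tri[1, 1]) - px * (tri[2, 2] - tri[1, 2])) / d
      if (l2 >= 0 && l3 >= 0 && l2 + l3 <= 1) {
        z <- tri[1, 3] + l2 * (tri[2, 3] - tri[1, 3]) + l3 * (tri[3, 3] - tri[1, 3])
        q <- i + n * (j - 1)
        crossings[[q]] <- c(crossings[[q]], z)
      }
    }
  }

  mask <- array(FALSE, c(n, n, nz))
  for (j in seq_len(n)) for (i in seq_len(n)) {
    cz <- crossings[[i + n * (j - 1)]]
    if (is.null(cz)) next
    ## odd number of crossings above a point => inside
    above <- vapply(zc, function(z) sum(cz > z) %% 2 == 1, logical(1))
    mask[i, j, ] <- above & (zc > 0)  # closed against the floor plane
  }
  new("SolidMask", values = mask, spacing = spacing, origin = c(origin, 0))
}

#' Export a height map as a closed ASCII STL mesh
#'
#' Writes the elevation surface triangulated over the grid plus a vertical
#' skirt and bottom cap so the solid is watertight. Intended to emulate scan
#' output for round-trip testing of [loadScanMesh()].
#'
#' @param hm a [HeightMap-class].
#' @param path output file (.stl).
#' @return `path`, invisibly.
#' @export
writeHeightMapSTL <- function(hm, path) {
  v <- hm@values
  sp <- hm@spacing
  ## pad by edge replication so the surface covers the full grid footprint
  ## (half a cell beyond the outermost cell centers)
  v <- rbind(v[1, ], v, v[nrow(v), ])
  v <- cbind(v[, 1], v, v[, ncol(v)])
  nx <- nrow(v); ny <- ncol(v)
  xc <- c(hm@origin[1], .axisCenters(nx - 2, sp, hm@origin[1]),
          hm@origin[1] + (nx - 2) * sp)
  yc <- c(hm@origin[2], .axisCenters(ny - 2, sp, hm@origin[2]),
          hm@origin[2] + (ny - 2) * sp)
  tri <- list()
  add <- function(a, b, c) tri[[length(tri) + 1L]] <<- rbind(a, b, c)
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    p00 <- c(xc[i], yc[j], v[i, j]);       p10 <- c(xc[i + 1], yc[j], v[i + 1, j])
    p01 <- c(xc[i], yc[j + 1], v[i, j + 1]); p11 <- c(xc[i + 1], yc[j + 1], v[i + 1, j + 1])
    add(p00, p10, p11); add(p00, p11, p01)
    ## bottom cap (z = 0), reversed orientation
    b00 <- c(xc[i], yc[j], 0); b10 <- c(xc[i + 1], yc[j], 0)
    b01 <- c(xc[i], yc[j + 1], 0); b11 <- c(xc[i + 1], yc[j + 1], 0)
    add(b00, b11, b10); add(b00, b01, b11)
  }
  ## vertical skirts on the four grid borders
  skirt <- function(p, q) { add(p, q, c(q[1], q[2], 0)); add(p, c(q[1], q[2], 0), c(p[1], p[2], 0)) }
  for (i in seq_len(nx - 1)) {
    skirt(c(xc[i], yc[1], v[i, 1]), c(xc[i + 1], yc[1], v[i + 1, 1]))
    skirt(c(xc[i + 1], yc[ny], v[i + 1, ny]), c(xc[i], yc[ny], v[i, ny]))
  }
  for (j in seq_len(ny - 1)) {
    skirt(c(xc[1], yc[j + 1], v[1, j + 1]), c(xc[1], yc[j], v[1, j]))
    skirt(c(xc[nx], yc[j], v[nx, j]), c(xc[nx], yc[j + 1], v[nx, j + 1]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid heightmap", con)
  for (tt in tri) {
    writeLines("facet normal 0 0 0", con)
    writeLines(" outer loop", con)
    for (r in 1:3)
      writeLines(sprintf("  vertex %.6f %.6f %.6f", tt[r, 1], tt[r, 2], tt[r, 3]), con)
    writeLines(" endloop", con)
    writeLines("endfacet", con)
  }
  writeLines("endsolid heightmap", con)
  invisible(path)
}

#' Crop or pad a solid mask to a centered cubic simulation domain
#'
#' Extracts the lateral region `|x|, |y| <= side/2` and extends the vertical
#' axis to `side` (filling with air above), matching the cubic humidity
#' simulation domain whose bottom face is the scanned setup.
#'
#' @param mask a [SolidMask-class].
#' @param side cube side in mm (default 18).
#' @return A [SolidMask-class] of the cubic domain.
#' @export
cropToCube <- function(mask, side = 18) {
  sp <- mask@spacing
  n <- round(side / sp)
  v <- mask@values
  xc <- .axisCenters(dim(v)[1], sp, mask@origin[1])
  yc <- .axisCenters(dim(v)[2], sp, mask@origin[2])
  half <- n * sp / 2
  i0 <- which.min(abs(xc - (-half + sp / 2)))
  j0 <- which.min(abs(yc - (-half + sp / 2)))
  if (i0 + n - 1 > length(xc) || j0 + n - 1 > length(yc))
    stop("mask does not cover the requested cube laterally")
  is <- i0:(i0 + n - 1); js <- j0:(j0 + n - 1)
  out <- array(FALSE, c(n, n, n))
  nzv <- min(dim(v)[3], n)
  out[, , seq_len(nzv)] <- v[is, js, seq_len(nzv)]
  new("SolidMask", values = out, spacing = sp,
      origin = c(xc[is[1]] - sp / 2, yc[js[1]] - sp / 2, 0))
}

#' Solid volume of a mask
#' @param mask a [SolidMask-class].
#' @return volume in mm^3.
#' @export
solidVolume <- function(mask) sum(mask@values) * mask@spacing^3
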