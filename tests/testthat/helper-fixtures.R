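# Shared fixture builders. Everything is generated in code at test time.

# solid sphere (or cavity) of radius R voxels centered in an n^3 grid
sphereMask <- function(R, n = 2 * R + 12, cavity = FALSE, spacing = 1) {
  xc <- (seq_len(n)) - (n + 1) / 2
  rr <- array(0, c(n, n, n))
  for (k in seq_len(n)) rr[, , k] <- sqrt(outer(xc^2, xc^2, "+") + xc[k]^2)
  v <- if (cavity) rr >= R else rr <= R
  new("SolidMask", values = v, spacing = spacing,
      origin = c(-n / 2, -n / 2, -n / 2) * spacing)
}

# flat slab of given height (voxels) in an nx x ny x nz grid
slabMask <- function(height = 8, nx = 24, ny = 24, nz = 24, spacing = 1) {
  v <- array(FALSE, c(nx, ny, nz))
  v[, , seq_len(height)] <- TRUE
  new("SolidMask", values = v, spacing = spacing,
      origin = c(-nx / 2, -ny / 2, 0) * spacing)
}

# sphere-in-far-field-shell scene for the Maxwell oracle: solid sphere of
# radius Rv held at h_surface, far-field shell at radius Rout held at h_top
sphereShellScene <- function(Rv, Rout = 4 * Rv, spacing = 1) {
  n <- as.integer(ceiling(2 * Rout / spacing) + 5)
  xs <- ((seq_len(n)) - (n + 1) / 2) * spacing
  solid <- array(FALSE, c(n, n, n))
  cold <- array(FALSE, c(n, n, n))
  rr <- array(0, c(n, n, n))
  for (k in seq_len(n)) {
    r2 <- outer(xs^2, xs^2, "+") + xs[k]^2
    rr[, , k] <- sqrt(r2)
    solid[, , k] <- r2 <= Rv^2
    cold[, , k] <- r2 >= Rout^2
  }
  mask <- new("SolidMask", values = solid, spacing = spacing,
              origin = c(-n / 2, -n / 2, -n / 2) * spacing)
  list(mask = mask, cold = cold, r = rr, n = n, Rv = Rv, Rout = Rout)
}

# concentric-shell closed form: h(r) between Dirichlet h_s at Ri and h_t at Ro
shellSolution <- function(r, Ri, Ro, hs = 100, ht = 70) {
  ht + (hs - ht) * (1 / r - 1 / Ro) / (1 / Ri - 1 / Ro)
}

# standard small scene stack for the humidity targets (0.2 mm, 18 mm cube)
buildCubeScene <- function(cue, spacing = 0.2, side = 18) {
  spec <- sceneSpec(cue)
  hm <- buildHeightMap(spec, spacing, extent = side / 2 + 2)
  mask <- cropToCube(voxelize(hm, spacing), side)
  list(spec = spec, mask = mask)
}

# direct finite-difference quadrature of the growth rate on a field: an
# independent oracle for the one-step update (mirror boundaries, lattice
# units), written with plain R array shifts
oracleGrowthRate <- function(f, d) {
  dm <- dim(f)
  shm <- function(a, di, dj, dk) {
    ix <- function(m, dd) { i <- seq_len(m) + dd; i[i < 1] <- 1 - i[i < 1]
                            i[i > m] <- 2 * m - i[i > m] + 1; i }
    a[ix(dm[1], di), ix(dm[2], dj), ix(dm[3], dk)]
  }
  lap <- function(a) shm(a, 1, 0, 0) + shm(a, -1, 0, 0) + shm(a, 0, 1, 0) +
    shm(a, 0, -1, 0) + shm(a, 0, 0, 1) + shm(a, 0, 0, -1) - 6 * a
  L1 <- lap(f)
  f * (1 - f) * (-d * L1 - lap(L1))
}

# tiny rendered timelapse shared by pipeline-level tests (cached per session)
smallPillarSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- sceneSpec("pillars")
      bp <- behaviorParams(seed = 7, collectionRate = 0.012,
                           depositionRate = 0.012)
      cache <<- list(spec = spec,
                     sim = renderSequence(spec, bp, duration = 2320))
    }
    cache
  }
})
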