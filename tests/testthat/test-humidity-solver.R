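test_that("an empty floor gives the exact linear profile", {
  m <- new("SolidMask", values = array(FALSE, c(10, 10, 18)), spacing = 1,
           origin = c(-5, -5, 0))
  hf <- solveLaplace(m, domainHeight = 18)
  h <- fieldValues(hf)
  zc <- (1:18) - 0.5
  expect_equal(h[5, 5, ], 100 - 30 * zc / 18, tolerance = 1e-8)
  gm <- gradientMap(hf)
  expect_equal(range(gm@values), rep(30 / 18 / 100, 2), tolerance = 1e-8)
  fb <- fluxBalance(hf)
  expect_lt(fb$relDiff, 1e-8)
})

test_that("the sphere solution matches the Maxwell closed form", {
  sc <- sphereShellScene(10, 40)
  hf <- solveLaplace(sc$mask, domainHeight = sc$n, bottomWet = FALSE,
                     cold = sc$cold)
  h <- fieldValues(hf)
  sel <- sc$r >= sc$Rv + 1 & sc$r <= 3 * sc$Rv & !is.na(h)
  exact <- shellSolution(sc$r[sel], sc$Rv, sc$Rout)
  expect_lt(max(abs(h[sel] - exact) / exact), 0.02)
  ## surface flux uniform over the sphere (modulo staircase scatter)
  sf <- surfaceFlux(hf)
  expect_lt(sd(sf$flux) / mean(sf$flux), 0.35)
})

test_that("surface flux scales as 1/R across sphere radii", {
  radii <- c(6, 9, 13)
  fl <- vapply(radii, function(R) {
    sc <- sphereShellScene(R, 4 * R)
    hf <- solveLaplace(sc$mask, domainHeight = sc$n, bottomWet = FALSE,
                       cold = sc$cold)
    mean(surfaceFlux(hf)$flux)
  }, numeric(1))
  p <- coef(lm(log(fl) ~ log(radii)))[2]
  expect_equal(unname(p), -1, tolerance = 0.1)
})

test_that("gradient maps converge under grid refinement", {
  probeMax <- function(sp) {
    sc <- sphereShellScene(8, 32, spacing = sp)
    hf <- solveLaplace(sc$mask, domainHeight = sc$n * sp, bottomWet = FALSE,
                       cold = sc$cold)
    gm <- gradientMap(hf, bottomWet = FALSE)
    probe <- sc$r >= 1.5 * 8 & sc$r <= 2 * 8
    max(gm@values[probe], na.rm = TRUE)
  }
  a <- probeMax(1)
  b <- probeMax(0.5)
  expect_lt(abs(b - a) / a, 0.03)
})

test_that("the discrete maximum principle holds on every scene", {
  scenes <- list(
    slab = slabMask(6),
    sphere = sphereMask(8, n = 30),
    pillars = buildCubeScene("pillars", spacing = 0.4)$mask,
    wall = buildCubeScene("wall", spacing = 0.4)$mask)
  for (nm in names(scenes)) {
    m <- scenes[[nm]]
    hf <- solveLaplace(m, domainHeight = dim(m@values)[3] * spacing(m))
    h <- fieldValues(hf)
    expect_gte(min(h, na.rm = TRUE), 70 - 1e-6)
    expect_lte(max(h, na.rm = TRUE), 100 + 1e-6)
    fb <- fluxBalance(hf)
    expect_lt(fb$relDiff, 0.01)
  }
})

test_that("disconnected air pockets are rejected", {
  v <- array(FALSE, c(8, 8, 10))
  v[, , 4] <- TRUE         # solid sheet sealing the domain
  v[4, 4, 2] <- FALSE      # (already air) pocket below the sheet
  m <- new("SolidMask", values = v, spacing = 1, origin = c(0, 0, 0))
  expect_error(solveLaplace(m, domainHeight = 10), "disconnected")
})

test_that("boundary-layer gradient is deltaH over delta", {
  expect_identical(boundaryLayerGradient(), 0.15)
  expect_identical(boundaryLayerGradient(boundaryLayerParams(deltaH = 0)), 0)
  expect_identical(boundaryLayerGradient(boundaryLayerParams(delta = 1,
                                                             deltaH = 100)), 1)
  expect_error(boundaryLayerParams(delta = -1) |> validObject(), "delta")
})

test_that("amplification is a max-over-tip to median-reference ratio", {
  g <- array(0.017, c(10, 10, 10))
  gm <- new("GradientMap", values = g, solid = array(FALSE, c(10, 10, 10)),
            spacing = 1, origin = c(0, 0, 0))
  tip <- array(FALSE, c(10, 10, 10)); tip[5, 5, 5] <- TRUE
  ref <- array(FALSE, c(10, 10, 10)); ref[2, 2, 2] <- TRUE
  expect_equal(amplification(gm, tip, ref), 1)
  expect_error(amplification(gm, tip, tip), "disjoint")
  expect_error(amplification(gm, array(FALSE, c(10, 10, 10)), ref),
               "nonempty")
})

test_that("wall gradients peak at the lateral tips of the top edge", {
  sc <- buildCubeScene("wall", spacing = 0.4)
  hf <- solveLaplace(sc$mask, domainHeight = 18)
  gm <- gradientMap(hf)
  ws <- wallEdgeStats(gm, sc$mask, sc$spec)
  expect_gt(ws$tipMax, ws$midEdgeMedian)
  expect_gt(ws$cornerRatio, 1)
  ## the edge profile has its maxima at the two ends
  prof <- ws$edgeProfile
  ok <- is.finite(prof$g)
  expect_gt(max(prof$g[ok & abs(prof$x) > 4]),
            max(prof$g[ok & abs(prof$x) <= 2]))
})

test_that("the wet disk edge concentrates evaporation like a drying drop", {
  ## disk on a dry plane: Dirichlet only on the clay, no-flux elsewhere
  spec <- sceneSpec("none")
  hm <- buildHeightMap(spec, 0.75, extent = spec@arenaRadius)
  mask <- voxelize(hm, 0.75, zmax = 3)
  hf <- solveLaplace(mask, domainHeight = 18, bottomWet = FALSE)
  sf <- surfaceFlux(hf)
  r <- sqrt(sf$x^2 + sf$y^2)
  top <- sf$k == max(sf$k)  # the disk top surface
  edge <- top & r >= 23 & r <= 25
  center <- top & r <= 10
  expect_gte(mean(sf$flux[edge]), 1.5 * mean(sf$flux[center]))
})

test_that("flux and curvature are rank-correlated", {
  ## pooled spheres: per-sphere mean flux and curvature are both ~ 1/R
  radii <- c(6, 9, 13)
  stats <- vapply(radii, function(R) {
    sc <- sphereShellScene(R, 4 * R)
    hf <- solveLaplace(sc$mask, domainHeight = sc$n, bottomWet = FALSE,
                       cold = sc$cold)
    sf <- surfaceFlux(hf)
    fc <- fluxCurvatureCorrelation(sf, sc$mask)
    c(flux = mean(sf$flux), rho = fc$rho)
  }, numeric(2))
  expect_identical(cor(stats["flux", ], 1 / radii, method = "spearman"), 1)
  ## within a single pillar scene the correlation is positive
  sc <- buildCubeScene("pillars", spacing = 0.4)
  hf <- solveLaplace(sc$mask, domainHeight = 18)
  fc <- fluxCurvatureCorrelation(surfaceFlux(hf), sc$mask)
  expect_gt(fc$rho, 0)
  ## degenerate (flat slab): flagged
  ms <- slabMask(6, nz = 18)
  hfs <- solveLaplace(ms, domainHeight = 18)
  fcs <- fluxCurvatureCorrelation(surfaceFlux(hfs), ms)
  expect_true(fcs$degenerate)
  expect_true(is.na(fcs$rho))
})
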