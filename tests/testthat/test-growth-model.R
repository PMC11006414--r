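test_that("initialization produces a smoothed, partly frozen field", {
  mask <- slabMask(8)
  p <- growthParams(smoothingSigma = 1.5)
  pf <- initializeField(mask, p)
  f <- fieldValues(pf)
  ## sigmoidal: 1 deep in the solid, 0 high in the air, monotone through the
  ## interface
  prof <- f[12, 12, ]
  expect_gt(prof[2], 0.999)
  expect_lt(prof[20], 1e-3)
  expect_true(all(diff(prof[2:20]) <= 1e-12))
  ## frozen = f > threshold at t = 0; deep clay frozen, interface band free
  expect_true(all(pf@frozen == (f > 0.85)))
  expect_true(pf@frozen[12, 12, 2])
  expect_false(pf@frozen[12, 12, 9])

  ## sigma -> 0 gives the binary mask back
  pf0 <- initializeField(mask, growthParams(smoothingSigma = 0))
  expect_identical(fieldValues(pf0), array(as.numeric(mask@values),
                                           dim(mask@values)))
  ## degenerate masks rejected
  all1 <- new("SolidMask", values = array(TRUE, c(4, 4, 4)), spacing = 1,
              origin = c(0, 0, 0))
  expect_error(initializeField(all1, p), "both solid and air")
})

test_that("curvature operators recover closed-form curvatures", {
  ## solid sphere: divergence variant ~ 2/R at the interface, positive
  mask <- sphereMask(10, n = 44)
  pf <- initializeField(mask, growthParams(smoothingSigma = 1.5))
  f <- fieldValues(pf)
  K <- meanCurvature(f, "divergence")
  band <- abs(f - 0.5) < 0.1
  expect_equal(mean(K[band]), 2 / 10, tolerance = 0.1)
  expect_true(all(K[band] > 0))

  ## solid cylinder: ~ 1/R
  n <- 40
  xc <- (1:n) - (n + 1) / 2
  rho <- sqrt(outer(xc^2, xc^2, "+"))
  cyl <- array(rho <= 10, c(n, n, 12))
  mc <- new("SolidMask", values = cyl, spacing = 1, origin = c(0, 0, 0))
  fc <- fieldValues(initializeField(mc, growthParams(smoothingSigma = 1.5)))
  Kc <- meanCurvature(fc, "divergence")
  bandc <- abs(fc - 0.5) < 0.1
  bandc[, , c(1:3, 10:12)] <- FALSE  # keep away from the z boundaries
  expect_equal(mean(Kc[bandc]), 1 / 10, tolerance = 0.1)

  ## flat slab: zero at the interface
  ms <- slabMask(8)
  fs <- fieldValues(initializeField(ms, growthParams(smoothingSigma = 1.5)))
  Ks <- meanCurvature(fs, "divergence")
  expect_lt(max(abs(Ks[abs(fs - 0.5) < 0.2])), 1e-8)
})

test_that("laplacian and exact-divergence curvatures agree at the interface", {
  for (R in c(10, 14)) {
    pf <- initializeField(sphereMask(R, n = 2 * R + 24),
                          growthParams(smoothingSigma = 1.5))
    f <- fieldValues(pf)
    Kl <- meanCurvature(f, "laplacian")
    Kd <- meanCurvature(f, "divergence")
    d <- dim(f)
    sh <- function(a, dd, ax) {
      ix <- pmin(pmax(seq_len(d[ax]) + dd, 1), d[ax])
      if (ax == 1) a[ix, , ] else if (ax == 2) a[, ix, ] else a[, , ix]
    }
    gn <- sqrt(((sh(f, 1, 1) - sh(f, -1, 1)) / 2)^2 +
               ((sh(f, 1, 2) - sh(f, -1, 2)) / 2)^2 +
               ((sh(f, 1, 3) - sh(f, -1, 3)) / 2)^2)
    band <- abs(f - 0.5) < 0.1 & gn > 0.05
    ## band means of the two curvature estimates within 15%
    expect_equal(mean(Kl[band] / gn[band]), mean(Kd[band]), tolerance = 0.15)
  }
})

test_that("a flat binary interface is exactly stationary", {
  mask <- slabMask(8)
  p <- growthParams(d = 0.5, smoothingSigma = 0)
  pf <- initializeField(mask, p)
  one <- growthStep(pf, p, 1)
  expect_lt(max(abs(fieldValues(one) - fieldValues(pf))), 1e-10)
  hundred <- growthStep(pf, p, 100)
  expect_lt(max(abs(fieldValues(hundred) - fieldValues(pf))), 1e-8)
})

test_that("a smoothed flat interface does not move", {
  mask <- slabMask(8)
  p <- growthParams(d = 0.5, smoothingSigma = 1.5)
  pf <- initializeField(mask, p)
  pfT <- growthStep(pf, p, 200)
  ## profile shape relaxes but the level-set position stays put
  expect_lt(max(abs(interfaceHeight(pfT) - interfaceHeight(pf))), 0.2)
})

test_that("uniform phases are fixed points", {
  for (val in c(0, 1)) {
    pf <- new("PhaseField", values = array(val, c(8, 8, 8)),
              frozen = array(FALSE, c(8, 8, 8)), spacing = 1,
              origin = c(0, 0, 0), time = 0)
    p <- growthParams(d = 1)
    out <- growthStep(pf, p, 5)
    expect_identical(fieldValues(out), fieldValues(pf))
  }
})

test_that("the one-step update matches a direct quadrature of the rate", {
  ## hemispherical solid bump on a slab, analytic initial field
  n <- 32
  xc <- (1:n) - (n + 1) / 2
  elev <- matrix(4, n, n)
  bump <- sqrt(outer(xc^2, xc^2, "+"))
  elev <- elev + ifelse(bump <= 8, sqrt(pmax(8^2 - bump^2, 0)), 0)
  f <- array(0, c(n, n, n))
  for (k in 1:n) f[, , k] <- 1 / (1 + exp((k - 0.5 - elev) / 2))
  p <- growthParams(d = 1)
  pf <- new("PhaseField", values = f, frozen = array(FALSE, c(n, n, n)),
            spacing = 1, origin = c(-n / 2, -n / 2, 0), time = 0)
  one <- growthStep(pf, p, 1)
  oracle <- f + p@dt * oracleGrowthRate(f, p@d)
  oracle <- pmin(pmax(oracle, 0), 1)
  expect_equal(fieldValues(one), array(oracle, dim(f)), tolerance = 1e-12)
  ## the curvature (growth) term is positive over the convex bump interface
  dm <- dim(f)
  shm <- function(a, di, dj, dk) {
    ix <- function(m, dd) { i <- seq_len(m) + dd; i[i < 1] <- 1 - i[i < 1]
                            i[i > m] <- 2 * m - i[i > m] + 1; i }
    a[ix(dm[1], di), ix(dm[2], dj), ix(dm[3], dk)]
  }
  lapf <- shm(f, 1, 0, 0) + shm(f, -1, 0, 0) + shm(f, 0, 1, 0) +
    shm(f, 0, -1, 0) + shm(f, 0, 0, 1) + shm(f, 0, 0, -1) - 6 * f
  growthTerm <- -p@d * f * (1 - f) * lapf
  capRegion <- array(FALSE, dm)
  for (k in 7:n) capRegion[, , k] <- bump < 6
  cap <- abs(f - 0.5) < 0.1 & capRegion
  expect_gt(mean(growthTerm[cap]), 0)
  ## and the solid mass in the bump's bounding region increases after one
  ## step, as the oracle's integrated rate predicts
  bbox <- array(FALSE, dm)
  for (k in 7:n) bbox[, , k] <- bump < 9
  expect_gt(sum(oracleGrowthRate(f, p@d)[bbox]), 0)
  expect_gt(sum(fieldValues(one)[bbox]), sum(f[bbox]))
})

test_that("convex solid grows and a cavity erodes, as the rate predicts", {
  d <- 1.5
  p <- growthParams(d = d, smoothingSigma = 1.5)
  sph <- sphereMask(10, n = 48)
  pf <- initializeField(sph, p)
  pfT <- growthStep(pf, p, round(3 / p@dt))
  volS0 <- sum(fieldValues(pf) >= 0.5)
  volST <- sum(fieldValues(pfT) >= 0.5)
  expect_gt(volST, volS0)  # solid sphere accretes
  ## direct quadrature oracle: net rate over the solid is positive
  expect_gt(sum(oracleGrowthRate(fieldValues(pf), d)), 0)

  cav <- sphereMask(10, n = 48, cavity = TRUE)
  pfc <- initializeField(cav, p)
  ## keep the concave interface free: only deep solid frozen by threshold
  pfcT <- growthStep(pfc, p, round(3 / p@dt))
  volC0 <- sum(fieldValues(pfc) >= 0.5)
  volCT <- sum(fieldValues(pfcT) >= 0.5)
  expect_lt(volCT, volC0)  # concave solid erodes: the air hole grows
  expect_lt(sum(oracleGrowthRate(fieldValues(pfc), d)), 0)
})

test_that("the field stays in [0,1] and frozen voxels never change", {
  set.seed(42)
  mask <- slabMask(8)
  p <- growthParams(d = 1, smoothingSigma = 1.5)
  pf <- initializeField(mask, p)
  v <- fieldValues(pf) + array(rnorm(length(fieldValues(pf)), sd = 0.2),
                               dim(fieldValues(pf)))
  pf@values <- pmin(pmax(v, 0), 1)
  pfT <- growthStep(pf, p, 100)
  expect_gte(min(fieldValues(pfT)), 0)
  expect_lte(max(fieldValues(pfT)), 1)
  frozenDelta <- abs(fieldValues(pfT) - fieldValues(pf))[pf@frozen]
  expect_identical(max(frozenDelta), 0)
})

test_that("runs are deterministic and snapshot bookkeeping is exact", {
  mask <- sphereMask(8, n = 32)
  p <- growthParams(d = 1.5, tEnd = 2, snapshotTimes = c(0, 1, 2))
  pf <- initializeField(mask, p)
  s1 <- runGrowth(pf, p)
  s2 <- runGrowth(pf, p)
  expect_identical(lapply(s1, fieldValues), lapply(s2, fieldValues))
  expect_named(s1, c("t=0", "t=1", "t=2"))
  expect_identical(fieldValues(s1[[1]]), fieldValues(pf))
  ## t_end = 0: single snapshot equal to the input
  p0 <- growthParams(d = 1.5, tEnd = 0)
  expect_identical(fieldValues(runGrowth(pf, p0)[[1]]), fieldValues(pf))
})

test_that("emergent pattern spacing decreases with d", {
  cal <- calibrateD(0.45, candidates = c(0.89, 1.33, 1.78), seed = 2)
  lam <- cal$table$wavelength_mm
  expect_true(all(diff(lam) < 0))
})

test_that("deposition voxels are the newly solid set", {
  mask <- sphereMask(8, n = 28)
  p <- growthParams(d = 1.5)
  pf <- initializeField(mask, p)
  expect_equal(nrow(depositionVoxels(pf, pf)), 0)
  pf2 <- pf
  v <- fieldValues(pf2)
  stopifnot(v[4, 4, 4] < 0.5)
  v[4, 4, 4] <- 0.9
  pf2@values <- v
  dv <- depositionVoxels(pf, pf2)
  expect_equal(unname(dv[1, ]), c(4, 4, 4))
  ## grid mismatch rejected
  other <- initializeField(sphereMask(8, n = 30), p)
  expect_error(depositionVoxels(pf, other), "different grids")
})

test_that("radial profiling maps deposits to the original surface", {
  mask <- sphereMask(8, n = 28)
  p <- growthParams(d = 1.5)
  pf <- initializeField(mask, p)
  ## plant added voxels just above the sphere's equator ring
  pf2 <- pf
  v <- fieldValues(pf2)
  ctr <- (28 + 1) / 2
  for (ang in seq(0, 2 * pi, length.out = 12)) {
    i <- round(ctr + 9.5 * cos(ang)); j <- round(ctr + 9.5 * sin(ang))
    v[i, j, round(ctr)] <- 1
  }
  pf2@values <- v
  added <- depositionVoxels(pf, pf2)
  prof <- projectAndProfile(added, pf, planeAxis = "y", planeValue = 0,
                            slabHalfWidth = 14, binWidth = 1)
  expect_equal(max(prof@values), 1)  # max-normalized by construction
  ## all mass near the sphere radius
  expect_equal(prof@bins[which.max(prof@values)], 8, tolerance = 1.6)
  ## empty selection near a far plane is flagged by a zero-length profile
  empty <- projectAndProfile(added, pf, planeValue = 40, slabHalfWidth = 0.5)
  expect_length(empty@values, 0)
})

test_that("the stability bound rejects oversized time steps", {
  expect_error(growthParams(d = 1, dt = 1), "stability")
  expect_silent(validObject(growthParams(d = 1)))
})
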