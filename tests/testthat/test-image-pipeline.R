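# Synthetic frame stacks built in code: a flat background with planted
# pellet appearances/disappearances and transient "animal" blobs.

mkSeq <- function(nframes, npx = 60, cadence = 20, bg = 0.5) {
  frames <- array(bg, c(npx, npx, nframes))
  timelapseSequence(frames, (seq_len(nframes) - 1) * cadence, 0.15,
                    reference = matrix(bg, npx, npx))
}

test_that("frame extraction respects the native cadence", {
  seq <- mkSeq(40)
  sub <- extractFrames(seq, 80)
  expect_equal(dim(sub@frames)[3], 10)
  expect_equal(sub@times, seq(0, by = 80, length.out = 10))
  ## interval equal to the cadence is the identity
  same <- extractFrames(seq, 20)
  expect_identical(same@frames, seq@frames)
  expect_error(extractFrames(seq, 70), "multiple")
  expect_error(extractFrames(seq, 10), "below the native cadence")
})

test_that("static sequences produce all-zero change images", {
  seq <- mkSeq(40)
  ch <- detectChanges(extractFrames(seq, 80))
  expect_equal(dim(ch$change)[3], 0)  # 10 frames -> (10-10+1)/10 -> 0 windows
  seq2 <- mkSeq(120)
  ch2 <- detectChanges(extractFrames(seq2, 80))
  expect_equal(dim(ch2$change)[3], 2)
  expect_true(all(ch2$change == 0))
})

test_that("window accounting follows valid-mode medians", {
  for (n in c(9, 10, 19, 20, 29, 45)) {
    ch <- detectChanges(mkSeq(n, npx = 12))
    expect_equal(dim(ch$change)[3], max((n - 10 + 1) %/% 10, 0))
  }
})

test_that("persistent changes survive and transients are suppressed", {
  seq <- mkSeq(30, npx = 40)
  ## pellet removed from frame 8 onward: persistent dark square
  seq@frames[10:12, 10:12, 8:30] <- 0.2
  ## transient bright blob for 3 frames (a passing animal)
  seq@frames[25:29, 25:29, 12:14] <- 0.9
  ch <- detectChanges(seq)  # native cadence already 20 s; 30 frames -> 2 win
  expect_equal(dim(ch$change)[3], 2)
  w2 <- ch$change[, , 2]
  expect_lt(w2[11, 11], -0.25)        # dark trace present
  expect_equal(w2[27, 27], 0)         # transient gone
  w1 <- ch$change[, , 1]
  expect_equal(w1[27, 27], 0)
})

test_that("the area filter keeps the closed interval [10, 400] px", {
  npx <- 120
  img <- matrix(0, npx, npx)
  blob <- function(i0, j0, npix) {
    ## roughly square blob of exactly npix pixels
    side <- ceiling(sqrt(npix))
    cells <- head(as.matrix(expand.grid(i0:(i0 + side - 1),
                                        j0:(j0 + side - 1))), npix)
    img[cells] <<- 1
  }
  blob(5, 5, 9)      # excluded: below 10
  blob(30, 30, 10)   # retained: boundary
  blob(60, 60, 400)  # retained: boundary
  blob(90, 5, 401)   # excluded: above 400
  changes <- list(change = array(img, c(npx, npx, 1)), windowLength = 800,
                  pixelPitch = 0.15, origin = c(-9, -9))
  ev <- extractEvents(changes, "deposition", threshold = 0.5)
  expect_equal(sort(ev$components$area), c(10, 400))
  ## nothing above threshold -> zero components
  ev0 <- extractEvents(list(change = array(0, c(20, 20, 1)),
                            windowLength = 800, pixelPitch = 0.15,
                            origin = c(-1.5, -1.5)), "deposition",
                       threshold = 0.5)
  expect_equal(nrow(ev0$components), 0)
})

test_that("accumulation bins event mass on the analysis grid", {
  npx <- 200  # 30 mm field at 0.15 mm/px
  planted <- list(c(-8, 3), c(5, -6), c(0, 9))
  img <- matrix(0, npx, npx)
  for (p in planted) {
    i <- round((p[1] + 15) / 0.15); j <- round((p[2] + 15) / 0.15)
    img[i + (-2:2), j + (-2:2)] <- 1
  }
  changes <- list(change = array(img, c(npx, npx, 1)), windowLength = 800,
                  pixelPitch = 0.15, origin = c(-15, -15))
  ev <- extractEvents(changes, "deposition", threshold = 0.5)
  am <- accumulateEvents(ev, cellSize = 0.75, extent = 15)
  expect_equal(sum(am@cumulative), 3 * 25)  # area mode: 25 px per blob
  ## mass sits within one cell of each planted location, nowhere else
  for (p in planted) {
    gi <- floor((p[1] - am@origin[1]) / 0.75) + 1
    gj <- floor((p[2] - am@origin[2]) / 0.75) + 1
    expect_gt(sum(am@cumulative[gi + (-1:1), gj + (-1:1)]), 0)
  }
  ## count mode: one unit per component
  amc <- accumulateEvents(ev, cellSize = 0.75, extent = 15, mode = "count")
  expect_equal(sum(amc@cumulative), 3)
  ## empty events give a zero map
  ev0 <- extractEvents(list(change = array(0, c(20, 20, 1)),
                            windowLength = 800, pixelPitch = 0.15,
                            origin = c(-1.5, -1.5)), "deposition",
                       threshold = 0.5)
  am0 <- accumulateEvents(ev0, cellSize = 0.75, extent = 1.5)
  expect_true(all(am0@cumulative == 0))
})

test_that("occupancy maps bin trajectory positions", {
  times <- seq(0, 1600, by = 20)
  ## one stationary animal -> a single nonzero cell
  traj <- data.frame(frame = seq_along(times), id = 1,
                     x = 100.3, y = 100.3)
  om <- occupancyMap(traj, times, 0.15, c(-15, -15), cellSize = 0.75,
                     extent = 15)
  expect_equal(sum(om@cumulative > 0), 1)
  expect_equal(sum(om@cumulative), length(times))
  ## empty table -> zero map
  om0 <- occupancyMap(traj[0, ], times, 0.15, c(-15, -15), cellSize = 0.75,
                      extent = 15)
  expect_true(all(om0@cumulative == 0))
  ## positions outside the arena are dropped and counted
  traj2 <- traj
  traj2$x[1:5] <- 1e4
  om2 <- occupancyMap(traj2, times, 0.15, c(-15, -15), cellSize = 0.75,
                      extent = 15, arenaRadius = 14)
  expect_equal(attr(om2, "dropped"), 5)
  expect_equal(sum(om2@cumulative), length(times) - 5)
})

test_that("uniform occupancy is statistically uniform on the grid", {
  set.seed(11)
  n <- 20000
  times <- c(0, 800)
  traj <- data.frame(frame = 1, id = 1,
                     x = runif(n, 0, 200), y = runif(n, 0, 200))
  om <- occupancyMap(traj, times, 0.15, c(-15, -15), cellSize = 5,
                     extent = 15)
  counts <- as.numeric(om@cumulative)
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("mean normalization and conditionals obey their identities", {
  m <- matrix(2, 8, 8)
  expect_true(all(normalizeByMean(m) == 1))
  m2 <- matrix(0, 5, 5); m2[3, 3] <- 7
  expect_equal(normalizeByMean(m2)[3, 3], 25)
  set.seed(3)
  m3 <- matrix(runif(64), 8, 8)
  expect_equal(mean(normalizeByMean(m3)), 1)
  expect_error(normalizeByMean(matrix(0, 4, 4)), "zero")

  o <- matrix(runif(64, 0.5, 2), 8, 8)
  a <- matrix(runif(64), 8, 8)
  cm <- conditionalMap(a, o)
  expect_equal(cm$values * o, a, tolerance = 1e-12)
  expect_true(all(cm$valid))
  ## activity equal to occupancy gives ratio 1
  cm1 <- conditionalMap(o, o)
  expect_true(all(abs(cm1$values - 1) < 1e-12))
  ## zero-occupancy cells are masked
  o2 <- o; o2[1, 1] <- 0
  cm2 <- conditionalMap(a, o2, eps = 1e-9)
  expect_true(is.na(cm2$values[1, 1]))
  expect_false(cm2$valid[1, 1])
})

test_that("radial densities are per-area and sum to one", {
  m <- matrix(1, 40, 40)
  rp <- radialDensity(m, cellSize = 0.75)
  expect_equal(sum(rp@values), 1)
  ## uniform map -> flat per-unit-area profile over covered radii
  full <- rp@bins < 0.75 * 18  # annuli fully inside the grid
  expect_lt(diff(range(rp@values[full])) / mean(rp@values[full]), 0.15)
  ## ring-concentrated map -> dominant bin at the ring radius
  m2 <- matrix(0, 40, 40)
  xc <- (-20:19 + 0.5) * 0.75
  rr <- sqrt(outer(xc^2, xc^2, "+"))
  m2[rr >= 9 & rr <= 10] <- 5
  rp2 <- radialDensity(m2, cellSize = 0.75)
  expect_equal(rp2@bins[which.max(rp2@values)], 9.5, tolerance = 0.8)
})

test_that("cross-sections are max-normalized cuts", {
  m <- matrix(4, 20, 20)
  cs <- crossSection(m, cellSize = 0.75)
  expect_true(all(cs@values == 1))
  ## peaked map: peak position preserved on the cut
  m2 <- matrix(0, 41, 41)
  xc <- (-20:20) * 0.75
  j0 <- 21
  m2[which.min(abs(xc - 4)), j0] <- 3
  m2[which.min(abs(xc + 4)), j0] <- 2
  cs2 <- crossSection(m2, cellSize = 0.75, axis = "x", value = 0)
  expect_equal(max(cs2@values), 1)
  expect_equal(abs(cs2@bins[which.max(cs2@values)]), 4, tolerance = 0.4)
  expect_error(crossSection(m, cellSize = 0.75, value = 100), "intersect")
})
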