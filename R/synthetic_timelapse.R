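## Ground-truth timelapse generator: renders a brown clay disk with a band
## of grey pellets, moving elongated animal blobs, and planted
## collection/deposition events whose placement follows a configurable
## stimulus field, together with the trajectory table and event log the
## analysis pipeline expects. Everything is driven by one RNG seed, so
## identical seeds give bitwise-identical output.

#' Behavioral parameters of the synthetic generator
#'
#' @slot nTermites number of moving worker blobs (default 50).
#' @slot nSoldiers additional blobs that move but never build (default 5).
#' @slot alpha stimulus exponent: deposition sites are sampled with
#'   probability proportional to `stimulus^alpha`; 0 = uniform.
#' @slot collectionRate,depositionRate planted events per second.
#' @slot noiseSd per-pixel Gaussian noise sd (intensity units).
#' @slot pelletContrast intensity difference pellet vs clay.
#' @slot stepSd random-walk step sd per frame (mm).
#' @slot bodyLength,bodyWidth blob axes (mm).
#' @slot seed RNG seed.
#' @export
setClass("BehaviorParams", representation(
  nTermites = "numeric", nSoldiers = "numeric", alpha = "numeric",
  collectionRate = "numeric", depositionRate = "numeric", noiseSd = "numeric",
  pelletContrast = "numeric", stepSd = "numeric", bodyLength = "numeric",
  bodyWidth = "numeric", seed = "numeric"))

setValidity("BehaviorParams", function(object) {
  if (object@alpha < 0) return("alpha must be >= 0")
  if (object@collectionRate < 0 || object@depositionRate < 0)
    return("event rates must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' @param nTermites,nSoldiers,alpha,collectionRate,depositionRate,noiseSd,pelletContrast,stepSd,bodyLength,bodyWidth,seed see slots.
#' @rdname BehaviorParams-class
#' @export
behaviorParams <- function(nTermites = 50, nSoldiers = 5, alpha = 4,
                           collectionRate = 0.01, depositionRate = 0.01,
                           noiseSd = 0.01, pelletContrast = 0.3,
                           stepSd = 2, bodyLength = 4, bodyWidth = 1.5,
                           seed = 1) {
  new("BehaviorParams", nTermites = nTermites, nSoldiers = nSoldiers,
      alpha = alpha, collectionRate = collectionRate,
      depositionRate = depositionRate, noiseSd = noiseSd,
      pelletContrast = pelletContrast, stepSd = stepSd,
      bodyLength = bodyLength, bodyWidth = bodyWidth, seed = seed)
}

## intensity palette of the rendered scene; the floor tone is kept below the
## pellet tone so a pellet dropped at the disk edge still reads as a bright
## trace against either background
.palette <- list(petri = 0.60, clay = 0.45, termite = 0.22)

## draw a filled disc onto an image matrix (in place, returns matrix)
.drawDisc <- function(img, pitch, origin, cx, cy, radius, value) {
  n <- dim(img)
  i0 <- max(1L, floor((cx - radius - origin[1]) / pitch))
  i1 <- min(n[1], ceiling((cx + radius - origin[1]) / pitch) + 1L)
  j0 <- max(1L, floor((cy - radius - origin[2]) / pitch))
  j1 <- min(n[2], ceiling((cy + radius - origin[2]) / pitch) + 1L)
  if (i0 > i1 || j0 > j1) return(img)
  xi <- origin[1] + (i0:i1 - 0.5) * pitch
  yj <- origin[2] + (j0:j1 - 0.5) * pitch
  dd <- outer((xi - cx)^2, (yj - cy)^2, "+")
  img[i0:i1, j0:j1][dd <= radius^2] <- value
  img
}

## draw a filled rotated ellipse
.drawEllipse <- function(img, pitch, origin, cx, cy, a, b, theta, value) {
  n <- dim(img)
  r <- max(a, b)
  i0 <- max(1L, floor((cx - r - origin[1]) / pitch))
  i1 <- min(n[1], ceiling((cx + r - origin[1]) / pitch) + 1L)
  j0 <- max(1L, floor((cy - r - origin[2]) / pitch))
  j1 <- min(n[2], ceiling((cy + r - origin[2]) / pitch) + 1L)
  if (i0 > i1 || j0 > j1) return(img)
  xi <- origin[1] + (i0:i1 - 0.5) * pitch
  yj <- origin[2] + (j0:j1 - 0.5) * pitch
  dx <- outer(xi - cx, rep(1, length(yj)))
  dy <- outer(rep(1, length(xi)), yj - cy)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  img[i0:i1, j0:j1][u^2 + v^2 <= 1] <- value
  img
}

#' Surface stimulus field for deposition placement
#'
#' Projects a 3D stimulus onto the 2D arena grid: either the positive local
#' mean curvature of the substrate surface ("curvature") or the humidity-
#' gradient magnitude at the surface ("humidity_gradient"). The two agree on
#' topographic cues, but only the humidity source expresses the ring of
#' enhanced evaporation at the edge of the wet clay disk.
#'
#' @param mask a [SolidMask-class] covering the region of interest.
#' @param source "curvature" or "humidity_gradient".
#' @param gm a [GradientMap-class] (required for the humidity source).
#' @param sigma indicator smoothing in voxels for the curvature source.
#' @return list with `values` (matrix over the mask's lateral grid, >= 0),
#'   `spacing`, `origin`.
#' @export
stimulusField <- function(mask, source = c("curvature", "humidity_gradient"),
                          gm = NULL, sigma = 2) {
  source <- match.arg(source)
  solid <- mask@values
  d <- dim(solid)
  if (!is.null(gm) && !identical(dim(gm@values), d)) {
    dg <- dim(gm@values)
    if (all(dg[1:2] == d[1:2]) && dg[3] > d[3]) {
      ## solver padded the domain with air above; match it
      solid <- array(c(solid, rep(FALSE, prod(dg[1:2]) * (dg[3] - d[3]))), dg)
      d <- dg
    }
  }
  if (source == "curvature") {
    f <- array(cpp_blur3d(as.numeric(solid), d, sigma), d)
    K <- meanCurvature(f, "divergence") / mask@spacing  # mm^-1
    surf <- .surfaceAdjacentAir(solid)
    K[!surf] <- NA_real_
    vals <- apply(K, c(1, 2), function(col) {
      v <- col[is.finite(col)]
      if (!length(v)) 0 else max(v, 0)
    })
  } else {
    if (is.null(gm)) stop("humidity_gradient source requires a GradientMap")
    if (!identical(dim(gm@values), d))
      stop("gradient map grid does not match the mask")
    g <- gm@values
    surf <- .surfaceAdjacentAir(solid)
    g[!surf] <- NA_real_
    vals <- apply(g, c(1, 2), function(col) {
      v <- col[is.finite(col)]
      if (!length(v)) 0 else max(v)
    })
  }
  list(values = vals, spacing = mask@spacing,
       origin = mask@origin[1:2], source = source)
}

## sample n positions from a 2D stimulus map with exponent alpha,
## uniformly jittered within the chosen cell
.sampleStimulus <- function(stim, n, alpha) {
  w <- pmax(stim$values, 0)^alpha
  if (sum(w) <= 0) stop("stimulus field is identically zero")
  cells <- sample.int(length(w), n, replace = TRUE, prob = as.numeric(w))
  ij <- arrayInd(cells, dim(stim$values))
  sp <- stim$spacing
  cbind(x = stim$origin[1] + (ij[, 1] - 1 + runif(n)) * sp,
        y = stim$origin[2] + (ij[, 2] - 1 + runif(n)) * sp)
}

#' Render a synthetic building timelapse
#'
#' Produces frames at the native cadence: a static background (Petri dish,
#' clay disk, initial pellet band), moving elongated blobs following a
#' reflected random walk, planted pellet collections (a pellet in the band
#' disappears, chosen uniformly) and depositions (a pellet appears at a
#' location sampled from `stimulus^alpha`, or uniformly over the disk when
#' no stimulus is given), plus per-pixel Gaussian noise. Returns the
#' sequence, the trajectory table and the ground-truth event log.
#'
#' @param spec a [SceneSpec-class].
#' @param params a [BehaviorParams-class].
#' @param duration total time in seconds.
#' @param cadence frame interval in seconds (default 20).
#' @param pixelPitch mm per pixel (default 0.15).
#' @param stimulus optional output of [stimulusField()] for deposition
#'   placement.
#' @param nInitialPellets pellets rendered in the band at t = 0.
#' @param eventWindow fraction (lo, hi) of the duration within which events
#'   are scheduled, keeping them inside fully analyzed windows.
#' @return list with `seq` ([TimelapseSequence-class]), `trajectories`
#'   (data.frame frame, id, x, y in px) and `events` (data.frame kind,
#'   time_s, x_mm, y_mm, radius_px, contrast).
#' @export
renderSequence <- function(spec, params, duration, cadence = 20,
                           pixelPitch = 0.15, stimulus = NULL,
                           nInitialPellets = 150,
                           eventWindow = c(0.05, 0.75)) {
  stopifnot(is(spec, "SceneSpec"), is(params, "BehaviorParams"))
  set.seed(params@seed)
  R <- spec@arenaRadius
  npx <- ceiling(2 * R / pixelPitch)
  origin <- c(-npx * pixelPitch / 2, -npx * pixelPitch / 2)
  nframes <- floor(duration / cadence) + 1L
  times <- (seq_len(nframes) - 1) * cadence
  pelletR <- spec@pelletDiameter / 2
  pelletRpx <- pelletR / pixelPitch
  clay <- .palette$clay
  pelletVal <- clay + params@pelletContrast

  ## background: petri, disk, pellet band
  g <- .gridXY(npx, npx, pixelPitch, origin)
  rr <- sqrt(g$x^2 + g$y^2)
  bg <- matrix(.palette$petri, npx, npx)
  bg[rr <= spec@diskRadius] <- clay
  band <- spec@pelletBand
  th <- runif(nInitialPellets, 0, 2 * pi)
  rad <- sqrt(runif(nInitialPellets, band[1]^2, band[2]^2))
  pellets <- data.frame(x = rad * cos(th), y = rad * sin(th), present = TRUE)
  for (p in seq_len(nInitialPellets))
    bg <- .drawDisc(bg, pixelPitch, origin, pellets$x[p], pellets$y[p],
                    pelletR, pelletVal)

  ## schedule events
  span <- duration * eventWindow
  nCol <- rpois(1, params@collectionRate * duration)
  nDep <- rpois(1, params@depositionRate * duration)
  nCol <- min(nCol, nInitialPellets)
  events <- list()
  if (nCol > 0) {
    pick <- sample.int(nInitialPellets, nCol)
    events[[1]] <- data.frame(
      kind = "collection", time_s = sort(runif(nCol, span[1], span[2])),
      x_mm = pellets$x[pick], y_mm = pellets$y[pick])
  }
  if (nDep > 0) {
    if (!is.null(stimulus) && params@alpha > 0) {
      xy <- .sampleStimulus(stimulus, nDep, params@alpha)
    } else {
      thd <- runif(nDep, 0, 2 * pi)
      rd <- sqrt(runif(nDep, 0, (0.9 * spec@diskRadius)^2))
      xy <- cbind(x = rd * cos(thd), y = rd * sin(thd))
    }
    events[[length(events) + 1L]] <- data.frame(
      kind = "deposition", time_s = sort(runif(nDep, span[1], span[2])),
      x_mm = xy[, 1], y_mm = xy[, 2])
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(0), time_s = numeric(0), x_mm = numeric(0),
               y_mm = numeric(0))
  if (nrow(events)) {
    events$radius_px <- pelletRpx
    events$contrast <- ifelse(events$kind == "deposition",
                              params@pelletContrast, -params@pelletContrast)
  } else {
    events$radius_px <- numeric(0); events$contrast <- numeric(0)
  }

  ## animal blobs: correlated (persistent-heading) walk inside the arena;
  ## per-frame displacement stepSd mm with heading noise, so a blob clears
  ## its own footprint between analysis frames and the temporal median can
  ## suppress it
  nb <- params@nTermites + params@nSoldiers
  bx <- runif(nb, -0.7, 0.7) * R
  by <- runif(nb, -0.7, 0.7) * R
  heading <- runif(nb, 0, 2 * pi)
  frames <- array(0, c(npx, npx, nframes))
  traj <- vector("list", nframes)
  cur <- bg
  for (t in seq_len(nframes)) {
    ## apply events that occurred since the previous frame
    if (nrow(events)) {
      due <- which(events$time_s <= times[t] & events$time_s >
                     (if (t == 1) -Inf else times[t - 1]))
      for (e in due) {
        val <- if (events$kind[e] == "collection") clay else pelletVal
        cur <- .drawDisc(cur, pixelPitch, origin, events$x_mm[e],
                         events$y_mm[e], pelletR, val)
      }
    }
    ## move blobs
    heading <- heading + rnorm(nb, sd = 0.4)
    stepx <- params@stepSd * cos(heading)
    stepy <- params@stepSd * sin(heading)
    bx <- bx + stepx; by <- by + stepy
    out <- sqrt(bx^2 + by^2) > 0.95 * R
    bx[out] <- bx[out] - 2 * stepx[out]
    by[out] <- by[out] - 2 * stepy[out]
    heading[out] <- heading[out] + pi
    img <- cur
    theta <- heading
    for (b in seq_len(nb))
      img <- .drawEllipse(img, pixelPitch, origin, bx[b], by[b],
                          params@bodyLength / 2, params@bodyWidth / 2,
                          theta[b], .palette$termite)
    if (params@noiseSd > 0)
      img <- img + matrix(rnorm(npx * npx, sd = params@noiseSd), npx, npx)
    frames[, , t] <- img
    traj[[t]] <- data.frame(frame = t, id = seq_len(nb),
                            x = (bx - origin[1]) / pixelPitch + 0.5,
                            y = (by - origin[2]) / pixelPitch + 0.5)
  }
  seqc <- timelapseSequence(frames, times, pixelPitch, reference = bg,
                            origin = origin)
  list(seq = seqc, trajectories = do.call(rbind, traj), events = events)
}

#' Run the full analysis pipeline on a rendered sequence
#'
#' Convenience wrapper: subsample, detect changes, extract collection and
#' deposition events, accumulate heatmaps, and build the occupancy map.
#'
#' @param sim output of [renderSequence()].
#' @param spec the [SceneSpec-class] used to render it.
#' @param interval analysis cadence in s (default 80).
#' @param cellSize analysis cell in mm (default 0.75).
#' @param maskRadius analysis mask radius in mm (default: disk plus a 3 mm
#'   margin so activity at the disk edge is kept).
#' @param ... passed to [extractEvents()].
#' @return list with `collections`, `depositions` ([ActivityMap-class]),
#'   `occupancy`, and the intermediate `events` lists.
#' @export
analyzeSequence <- function(sim, spec, interval = 80, cellSize = 0.75,
                            maskRadius = spec@diskRadius + 3, ...) {
  sub <- extractFrames(sim$seq, interval)
  ch <- detectChanges(sub)
  npx <- dim(sim$seq@frames)[1]
  g <- .gridXY(npx, npx, sim$seq@pixelPitch, sim$seq@origin)
  diskMask <- sqrt(g$x^2 + g$y^2) <= maskRadius
  evC <- extractEvents(ch, "collection", mask = diskMask, ...)
  evD <- extractEvents(ch, "deposition", mask = diskMask, ...)
  extent <- npx * sim$seq@pixelPitch / 2
  mc <- accumulateEvents(evC, cellSize, extent, kind = "collection")
  md <- accumulateEvents(evD, cellSize, extent, kind = "deposition")
  occ <- occupancyMap(sim$trajectories, sim$seq@times, sim$seq@pixelPitch,
                      sim$seq@origin, cellSize, extent,
                      windowLength = ch$windowLength,
                      arenaRadius = spec@arenaRadius)
  list(collections = mc, depositions = md, occupancy = occ,
       collectionEvents = evC, depositionEvents = evD)
}

#' Fraction of planted events recovered by the pipeline
#'
#' An event counts as recovered when the cumulative heatmap carries mass
#' within `tol` cells of its true location.
#'
#' @param map an [ActivityMap-class] (cumulative grid is used).
#' @param events the ground-truth event log (rows of one kind).
#' @param tol tolerance in cells (default 1).
#' @return recovery fraction in [0, 1] (NaN when no events).
#' @export
eventRecovery <- function(map, events, tol = 1) {
  if (!nrow(events)) return(NaN)
  m <- map@cumulative
  cs <- map@cellSize
  hit <- vapply(seq_len(nrow(events)), function(e) {
    gi <- floor((events$x_mm[e] - map@origin[1]) / cs) + 1
    gj <- floor((events$y_mm[e] - map@origin[2]) / cs) + 1
    ii <- max(1, gi - tol):min(nrow(m), gi + tol)
    jj <- max(1, gj - tol):min(ncol(m), gj + tol)
    sum(m[ii, jj]) > 0
  }, logical(1))
  mean(hit)
}
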