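## Timelapse image analysis: background subtraction, temporal median
## filtering to suppress moving animals, windowed change images, connected-
## component event extraction with an area filter, and the gridded
## collection/deposition/occupancy probability maps and their conditionals.
##
## Image convention: frames are numeric matrices indexed [ix, iy] with pixel
## centers at x = origin[1] + (ix - 1/2) * pixelPitch (and likewise y), i.e.
## the same arena mm coordinates (origin at center, y up) as the geometry
## modules. Converting row-major, y-down image files to this convention is a
## single transpose-and-flip, done at load time.

#' Timelapse sequence container
#'
#' @slot frames 3D numeric array (nx px, ny px, n frames), grayscale in [0,1].
#' @slot times frame timestamps in seconds, strictly increasing.
#' @slot pixelPitch mm per pixel.
#' @slot reference the t=0 frame without animals (background).
#' @slot origin physical position (mm) of the image corner.
#' @export
setClass("TimelapseSequence", representation(
  frames = "array", times = "numeric", pixelPitch = "numeric",
  reference = "matrix", origin = "numeric"))

setValidity("TimelapseSequence", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3D array (x, y, t)")
  if (length(object@times) != d[3])
    return("times must have one entry per frame")
  if (d[3] > 1 && any(diff(object@times) <= 0))
    return("timestamps must be strictly increasing")
  if (!identical(dim(object@reference), d[1:2]))
    return("reference frame size must match the frames")
  if (object@pixelPitch <= 0) return("pixelPitch must be positive")
  TRUE
})

#' @param frames,times,pixelPitch,reference,origin see slots.
#' @rdname TimelapseSequence-class
#' @export
timelapseSequence <- function(frames, times, pixelPitch, reference,
                              origin = -dim(frames)[1:2] * pixelPitch / 2) {
  new("TimelapseSequence", frames = frames, times = times,
      pixelPitch = pixelPitch, reference = reference, origin = origin)
}

setMethod("show", "TimelapseSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("TimelapseSequence: %d frames %dx%d px @ %.3g mm/px, t = [%g, %g] s\n",
              d[3], d[1], d[2], object@pixelPitch, min(object@times),
              max(object@times)))
})

#' Activity / occupancy heatmap
#'
#' Per-window count grids and their cumulative sum on the standard analysis
#' grid (0.75 mm cells by default).
#'
#' @slot perWindow 3D array (cells x, cells y, windows).
#' @slot cumulative matrix: sum over windows.
#' @slot cellSize cell size in mm.
#' @slot origin grid corner (mm).
#' @slot windowLength window length in seconds.
#' @slot kind "collection", "deposition" or "occupancy".
#' @export
setClass("ActivityMap", representation(
  perWindow = "array", cumulative = "matrix", cellSize = "numeric",
  origin = "numeric", windowLength = "numeric", kind = "character"))

setValidity("ActivityMap", function(object) {
  if (any(object@perWindow < 0)) return("counts must be non-negative")
  if (!isTRUE(all.equal(apply(object@perWindow, c(1, 2), sum),
                        object@cumulative, check.attributes = FALSE)))
    return("cumulative must equal the sum over windows")
  TRUE
})

setMethod("show", "ActivityMap", function(object) {
  d <- dim(object@perWindow)
  cat(sprintf("ActivityMap (%s): %dx%d cells @ %.3g mm, %d windows of %g s, total mass %.4g\n",
              object@kind, d[1], d[2], object@cellSize, d[3],
              object@windowLength, sum(object@cumulative)))
})

#' Subsample a timelapse to the analysis cadence
#'
#' Extracts frames at a fixed interval (default 80 s, an estimate of one
#' search-collection-deposition cycle).
#'
#' @param seq a [TimelapseSequence-class].
#' @param interval seconds; must be a positive multiple of the native cadence.
#' @return The subsampled [TimelapseSequence-class].
#' @export
extractFrames <- function(seq, interval = 80) {
  cad <- if (length(seq@times) > 1) diff(seq@times)[1] else interval
  if (interval < cad) stop("interval is below the native cadence (", cad, " s)")
  stepf <- interval / cad
  if (abs(stepf - round(stepf)) > 1e-9)
    stop("interval must be a multiple of the native cadence (", cad, " s)")
  keep <- seq(1L, dim(seq@frames)[3], by = as.integer(round(stepf)))
  timelapseSequence(seq@frames[, , keep, drop = FALSE], seq@times[keep],
                    seq@pixelPitch, seq@reference, seq@origin)
}

#' Windowed change images
#'
#' Subtracts the reference frame, suppresses moving animals with a trailing
#' temporal median (window `medianWindow`, valid mode: the first
#' `medianWindow - 1` frames produce no output), then block-averages the
#' median sequence over consecutive groups of `blockSize` images. With the
#' default 80 s cadence and 10/10 windows each change image integrates 800 s
#' of activity. Collected pellets leave negative (dark) traces, deposited
#' pellets positive (bright) traces.
#'
#' @param seq a subsampled [TimelapseSequence-class] (see [extractFrames()]).
#' @param medianWindow temporal median length (default 10).
#' @param blockSize images averaged per window (default 10).
#' @return list with `change` (3D array: x, y, window; zero windows when the
#'   sequence is too short), `windowLength` (s), `pixelPitch`, `origin`.
#' @export
detectChanges <- function(seq, medianWindow = 10L, blockSize = 10L) {
  d <- dim(seq@frames)
  cad <- if (d[3] > 1) diff(seq@times)[1] else 0
  npix <- d[1] * d[2]
  nmed <- d[3] - medianWindow + 1L
  nwin <- if (nmed > 0) nmed %/% blockSize else 0L
  if (nwin < 1)
    return(list(change = array(0, c(d[1], d[2], 0)),
                windowLength = blockSize * cad, pixelPitch = seq@pixelPitch,
                origin = seq@origin, noiseScale = 0))
  diffs <- matrix(seq@frames, npix, d[3]) - as.numeric(seq@reference)
  ## robust scale of the background-subtracted intensities (the reference
  ## scale for the "low threshold" binarisation), on a pixel subsample
  noiseScale <- mad(diffs[seq(1, length(diffs), by = 13)])
  med <- cpp_rolling_median(diffs, as.integer(medianWindow))
  change <- array(0, c(d[1], d[2], nwin))
  for (w in seq_len(nwin)) {
    cols <- ((w - 1) * blockSize + 1):(w * blockSize)
    change[, , w] <- matrix(rowMeans(med[, cols, drop = FALSE]), d[1], d[2])
  }
  list(change = change, windowLength = blockSize * cad,
       pixelPitch = seq@pixelPitch, origin = seq@origin,
       noiseScale = noiseScale)
}

#' Extract pellet events from change images
#'
#' Binarises each windowed change image at a low threshold (default: `k`
#' times the MAD of the background-subtracted frame intensities, as carried
#' by [detectChanges()]; fallback: MAD of the change image itself), labels
#' connected components, and retains components with area in the closed
#' interval `[areaMin, areaMax]` pixels (small = noise, large = clusters of
#' inactive animals).
#'
#' @param changes output of [detectChanges()].
#' @param polarity "collection" (dark traces) or "deposition" (bright traces,
#'   detected by sign inversion).
#' @param threshold absolute binarisation threshold; default `k * MAD`.
#' @param k MAD multiplier for the default threshold (default 3).
#' @param areaMin,areaMax inclusive component area limits in px (10, 400).
#' @param mask optional logical matrix restricting the analysis (e.g. the
#'   clay disk).
#' @return list with `components` (data.frame: window, label, area, x, y in
#'   mm at the component centroid) and `masks` (3D array of retained-event
#'   pixels per window).
#' @export
extractEvents <- function(changes, polarity = c("collection", "deposition"),
                          threshold = NULL, k = 3, areaMin = 10L,
                          areaMax = 400L, mask = NULL) {
  polarity <- match.arg(polarity)
  ch <- changes$change
  d <- dim(ch)
  masks <- array(FALSE, d)
  rows <- list()
  for (w in seq_len(d[3])) {
    img <- ch[, , w]
    v <- if (polarity == "collection") -img else img
    thr <- threshold
    if (is.null(thr)) {
      if (!is.null(changes$noiseScale) && changes$noiseScale > 0) {
        thr <- k * changes$noiseScale
      } else {
        pool <- if (is.null(mask)) as.numeric(img) else img[mask]
        thr <- k * mad(pool)
      }
    }
    if (thr <= 0) next
    bin <- v > thr
    if (!is.null(mask)) bin <- bin & mask
    if (!any(bin)) next
    lab <- as.matrix(EBImage::bwlabel(bin))
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= areaMin & areas <= areaMax)
    if (!length(keep)) next
    sel <- matrix(lab %in% keep, nrow(lab), ncol(lab))
    masks[, , w] <- sel
    idx <- which(sel, arr.ind = TRUE)
    labv <- lab[sel]
    cx <- tapply(idx[, 1], labv, mean)
    cy <- tapply(idx[, 2], labv, mean)
    rows[[length(rows) + 1L]] <- data.frame(
      window = w, label = as.integer(names(cx)),
      area = areas[as.integer(names(cx))],
      x = changes$origin[1] + (as.numeric(cx) - 0.5) * changes$pixelPitch,
      y = changes$origin[2] + (as.numeric(cy) - 0.5) * changes$pixelPitch)
  }
  comp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(window = integer(0), label = integer(0), area = integer(0),
               x = numeric(0), y = numeric(0))
  list(components = comp, masks = masks, pixelPitch = changes$pixelPitch,
       origin = changes$origin, windowLength = changes$windowLength)
}

#' Accumulate events onto the analysis grid
#'
#' Bins retained event pixels (mode "area": each pixel contributes its mass;
#' mode "count": one count per component at its centroid) onto a regular
#' grid of `cellSize` mm cells, per window and cumulatively.
#'
#' @param events output of [extractEvents()].
#' @param cellSize analysis cell size in mm (default 0.75, the pellet size).
#' @param extent grid half-width in mm (default from the image).
#' @param mode "area" or "count".
#' @param kind label stored in the result.
#' @return An [ActivityMap-class].
#' @export
accumulateEvents <- function(events, cellSize = 0.75, extent = NULL,
                             mode = c("area", "count"),
                             kind = "deposition") {
  mode <- match.arg(mode)
  d <- dim(events$masks)
  pitch <- events$pixelPitch
  if (is.null(extent)) extent <- d[1] * pitch / 2
  ng <- ceiling(2 * extent / cellSize)
  org <- c(-ng * cellSize / 2, -ng * cellSize / 2)
  nwin <- max(d[3], 1L)
  per <- array(0, c(ng, ng, d[3]))
  if (d[3] > 0) {
    for (w in seq_len(d[3])) {
      if (mode == "area") {
        idx <- which(events$masks[, , w], arr.ind = TRUE)
        if (!nrow(idx)) next
        x <- events$origin[1] + (idx[, 1] - 0.5) * pitch
        y <- events$origin[2] + (idx[, 2] - 0.5) * pitch
      } else {
        cc <- events$components[events$components$window == w, , drop = FALSE]
        if (!nrow(cc)) next
        x <- cc$x; y <- cc$y
      }
      gi <- pmin(pmax(floor((x - org[1]) / cellSize) + 1, 1), ng)
      gj <- pmin(pmax(floor((y - org[2]) / cellSize) + 1, 1), ng)
      for (q in seq_along(gi))
        per[gi[q], gj[q], w] <- per[gi[q], gj[q], w] + 1
    }
  }
  cum <- apply(per, c(1, 2), sum)
  new("ActivityMap", perWindow = per, cumulative = matrix(cum, ng, ng),
      cellSize = cellSize, origin = org,
      windowLength = events$windowLength, kind = kind)
}

#' Occupancy map from trajectory tables
#'
#' Bins tracked animal positions (native cadence) onto the analysis grid in
#' windows of `windowLength` seconds. Identities are not used. Positions
#' outside the arena are dropped and their count reported via attribute
#' `dropped`.
#'
#' @param traj data.frame with columns `frame`, `id`, `x`, `y` (pixels).
#' @param times frame timestamps (s), indexed by `frame`.
#' @param pixelPitch mm/px of the trajectory coordinates.
#' @param imageOrigin corner (mm) of the pixel coordinate system.
#' @param cellSize,extent analysis grid (as in [accumulateEvents()]).
#' @param windowLength window length in s (default 800).
#' @param arenaRadius positions farther than this from the center are
#'   dropped (default Inf).
#' @return An [ActivityMap-class] of kind "occupancy".
#' @export
occupancyMap <- function(traj, times, pixelPitch, imageOrigin, cellSize = 0.75,
                         extent, windowLength = 800, arenaRadius = Inf) {
  ng <- ceiling(2 * extent / cellSize)
  org <- c(-ng * cellSize / 2, -ng * cellSize / 2)
  tmax <- max(times)
  nwin <- max(1L, floor(tmax / windowLength + 1e-9))
  per <- array(0, c(ng, ng, nwin))
  dropped <- 0L
  if (nrow(traj)) {
    x <- imageOrigin[1] + (traj$x - 0.5) * pixelPitch
    y <- imageOrigin[2] + (traj$y - 0.5) * pixelPitch
    tt <- times[traj$frame]
    r <- sqrt(x^2 + y^2)
    ok <- r <= arenaRadius & is.finite(x) & is.finite(y)
    dropped <- sum(!ok)
    x <- x[ok]; y <- y[ok]; tt <- tt[ok]
    w <- pmin(pmax(floor(tt / windowLength) + 1, 1), nwin)
    gi <- pmin(pmax(floor((x - org[1]) / cellSize) + 1, 1), ng)
    gj <- pmin(pmax(floor((y - org[2]) / cellSize) + 1, 1), ng)
    for (q in seq_along(gi))
      per[gi[q], gj[q], w[q]] <- per[gi[q], gj[q], w[q]] + 1
  }
  cum <- apply(per, c(1, 2), sum)
  out <- new("ActivityMap", perWindow = per,
             cumulative = matrix(cum, ng, ng), cellSize = cellSize,
             origin = org, windowLength = windowLength, kind = "occupancy")
  attr(out, "dropped") <- dropped
  out
}

#' Normalize a map by its mean
#'
#' Divides by the mean over the analysis mask so the result has mean 1 there;
#' high-frequency cells read directly as values above 1.
#'
#' @param map matrix or [ActivityMap-class] (its cumulative grid is used).
#' @param mask optional logical matrix (default: all cells).
#' @return matrix of normalized values.
#' @export
normalizeByMean <- function(map, mask = NULL) {
  m <- if (is(map, "ActivityMap")) map@cumulative else map
  if (is.null(mask)) mask <- matrix(TRUE, nrow(m), ncol(m))
  mu <- mean(m[mask])
  if (!is.finite(mu) || mu == 0) stop("map mean over the mask is zero")
  m / mu
}

#' Conditional probability map
#'
#' Cellwise ratio activity / occupancy where occupancy is at least `eps`;
#' other cells are `NA` (masked). By construction
#' `conditional * occupancy = activity` on valid cells.
#'
#' @param activity,occupancy matrices or [ActivityMap-class] on the same grid.
#' @param eps minimum occupancy for a valid cell (default: any positive).
#' @return list with `values` (matrix, `NA` where invalid) and `valid`
#'   (logical matrix).
#' @export
conditionalMap <- function(activity, occupancy, eps = .Machine$double.eps) {
  a <- if (is(activity, "ActivityMap")) activity@cumulative else activity
  o <- if (is(occupancy, "ActivityMap")) occupancy@cumulative else occupancy
  if (!identical(dim(a), dim(o))) stop("grids differ between activity and occupancy")
  valid <- is.finite(o) & o >= eps & o > 0
  vals <- matrix(NA_real_, nrow(a), ncol(a))
  vals[valid] <- a[valid] / o[valid]
  list(values = vals, valid = valid)
}

#' Radial density profile of a map
#'
#' Sums cell values in annuli around `center`, divides by annulus area, and
#' normalizes the result to sum to 1 (cumulative activity per unit area as a
#' function of radius).
#'
#' @param map matrix or [ActivityMap-class].
#' @param cellSize cell size in mm (taken from the map when available).
#' @param center arena-frame center (mm).
#' @param binWidth radial bin width in mm (default one cell).
#' @return A sum-normalized [RadialProfile-class].
#' @export
radialDensity <- function(map, cellSize = NULL, center = c(0, 0),
                          binWidth = NULL) {
  if (is(map, "ActivityMap")) {
    if (is.null(cellSize)) cellSize <- map@cellSize
    org <- map@origin
    m <- map@cumulative
  } else {
    if (is.null(cellSize)) stop("cellSize required for plain matrices")
    m <- map
    org <- -dim(m) * cellSize / 2
  }
  if (is.null(binWidth)) binWidth <- cellSize
  g <- .gridXY(nrow(m), ncol(m), cellSize, org)
  r <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2)
  rmax <- max(r) + binWidth
  bin <- floor(r / binWidth) + 1L
  nb <- max(bin)
  sums <- vapply(seq_len(nb), function(b) sum(m[bin == b]), numeric(1))
  areas <- vapply(seq_len(nb), function(b) sum(bin == b) * cellSize^2, numeric(1))
  dens <- ifelse(areas > 0, sums / areas, 0)
  tot <- sum(dens)
  if (tot > 0) dens <- dens / tot
  new("RadialProfile", bins = (seq_len(nb) - 0.5) * binWidth, values = dens,
      normalization = if (tot > 0) "sum" else "none")
}

#' Cross-section of a map along a line
#'
#' Values of the cells adjacent to a horizontal or vertical line through the
#' grid, max-normalized by default (the convention used to overlay measured
#' depositions, surface curvature and simulated depositions on one cut).
#'
#' @param map matrix or [ActivityMap-class].
#' @param cellSize cell size in mm (from the map when available).
#' @param axis "x": the cut runs along x at `value` in y; "y": the converse.
#' @param value line position in mm.
#' @param normalize "max" or "none".
#' @return A [RadialProfile-class] with signed positions along the cut.
#' @export
crossSection <- function(map, cellSize = NULL, axis = c("x", "y"), value = 0,
                         normalize = c("max", "none")) {
  axis <- match.arg(axis)
  normalize <- match.arg(normalize)
  if (is(map, "ActivityMap")) {
    if (is.null(cellSize)) cellSize <- map@cellSize
    org <- map@origin
    m <- map@cumulative
  } else {
    if (is.null(cellSize)) stop("cellSize required for plain matrices")
    m <- map
    org <- -dim(m) * cellSize / 2
  }
  xc <- .axisCenters(nrow(m), cellSize, org[1])
  yc <- .axisCenters(ncol(m), cellSize, org[2])
  if (axis == "x") {
    j <- which.min(abs(yc - value))
    if (abs(yc[j] - value) > cellSize) stop("line does not intersect the grid")
    vals <- m[, j]
    pos <- xc
  } else {
    i <- which.min(abs(xc - value))
    if (abs(xc[i] - value) > cellSize) stop("line does not intersect the grid")
    vals <- m[i, ]
    pos <- yc
  }
  if (normalize == "max" && max(vals) > 0) vals <- vals / max(vals)
  new("RadialProfile", bins = pos, values = as.numeric(vals),
      normalization = if (normalize == "max" && max(vals) > 0) "max" else "none")
}
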