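## Plain-text interchange: heatmaps as TSV with a JSON metadata header line,
## trajectory tables as CSV, frames as PNG/TIFF directories.

#' Write an activity map as TSV
#'
#' First line is a `#`-prefixed JSON header (cell size, origin, window
#' length, kind); the rest is the cumulative grid, tab-separated, one row of
#' x-cells per line.
#'
#' @param map an [ActivityMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeActivityMapTSV <- function(map, path) {
  meta <- jsonlite::toJSON(list(cellSize = map@cellSize, origin = map@origin,
                                windowLength = map@windowLength,
                                kind = map@kind), auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  write.table(map@cumulative, con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a trajectory table
#'
#' CSV with header `frame,id,x,y` (pixel coordinates), the format produced
#' by multi-animal trackers.
#'
#' @param path CSV file.
#' @return data.frame with those columns.
#' @export
readTrajectoryCSV <- function(path) {
  df <- read.csv(path)
  need <- c("frame", "id", "x", "y")
  if (!all(need %in% names(df)))
    stop("trajectory table must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' Write timelapse frames to a directory
#'
#' One greyscale PNG (or TIFF) per frame, named `frame_%05d.png`, plus the
#' reference frame as `reference.png` and timestamps as `times.csv`. Note
#' that image files are row-major with y down; frames are transposed and
#' flipped accordingly, and [readFramesDir()] inverts the transform.
#'
#' @param seq a [TimelapseSequence-class].
#' @param dir output directory (created).
#' @param format "png" or "tiff".
#' @return `dir`, invisibly.
#' @export
writeFramesDir <- function(seq, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  pkg <- if (format == "png") "png" else "tiff"
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("package '", pkg, "' is required to write ", format, " frames")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tofile <- function(img, path) {
    ## arena (x right, y up) -> image (row down): transpose + flip rows
    m <- t(img)[dim(img)[2]:1, , drop = FALSE]
    m <- pmin(pmax(m, 0), 1)
    if (format == "png") png::writePNG(m, path) else tiff::writeTIFF(m, path)
  }
  d <- dim(seq@frames)
  for (t in seq_len(d[3]))
    tofile(seq@frames[, , t],
           file.path(dir, sprintf("frame_%05d.%s", t, format)))
  tofile(seq@reference, file.path(dir, paste0("reference.", format)))
  write.csv(data.frame(frame = seq_len(d[3]), time_s = seq@times),
            file.path(dir, "times.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read timelapse frames from a directory written by [writeFramesDir()]
#'
#' @param dir directory with `frame_*.png` / `frame_*.tiff`, `reference.*`
#'   and `times.csv`.
#' @param pixelPitch mm per pixel of the frames.
#' @return A [TimelapseSequence-class].
#' @export
readFramesDir <- function(dir, pixelPitch) {
  files <- sort(list.files(dir, "^frame_.*\\.(png|tiff?)$", full.names = TRUE))
  if (!length(files)) stop("no frame files in ", dir)
  ispng <- grepl("png$", files[1])
  pkg <- if (ispng) "png" else "tiff"
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("package '", pkg, "' is required")
  fromfile <- function(path) {
    m <- if (ispng) png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(m)) == 3) {  # RGB -> luminance
      m <- 0.2126 * m[, , 1] + 0.7152 * m[, , 2] + 0.0722 * m[, , 3]
    }
    t(m[nrow(m):1, , drop = FALSE])  # image (y down) -> arena (y up)
  }
  imgs <- lapply(files, fromfile)
  ref <- fromfile(list.files(dir, "^reference\\.", full.names = TRUE)[1])
  times <- read.csv(file.path(dir, "times.csv"))$time_s
  frames <- array(unlist(imgs), c(dim(imgs[[1]]), length(imgs)))
  timelapseSequence(frames, times, pixelPitch, ref)
}
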