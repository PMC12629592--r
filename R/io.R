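## Readers/writers and kymograph construction.  Movies go to multi-page
## TIFF (32-bit float, unit-scaled, with a JSON sidecar carrying the scale,
## calibration and channel layout); event tables and trajectories are CSV
## with a versioned schema line; configs round-trip through YAML.

EVENT_TABLE_SCHEMA <- "TipKineticsEventTable v1"

#' Write / read a movie stack as multi-page TIFF
#'
#' Pages are blocked by channel (all frames of channel 1, then channel 2,
#' ...).  Pixel values are stored as 32-bit float scaled to [0, 1]; the
#' per-file scale, calibration and channel layout live in a JSON sidecar
#' (\code{<path>.json}), so the round trip is lossless to single-float
#' precision (relative 1e-7).
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param path TIFF file path; the sidecar is written next to it.
#' @return \code{writeMovie}: the path, invisibly.  \code{readMovie}: a
#'   \linkS4class{MovieStack}.
#' @export
writeMovie <- function(movie, path) {
  stopifnot(is(movie, "MovieStack"))
  scale <- max(1e-12, max(vapply(movie@channels, max, 1)))
  pages <- list()
  for (ch in names(movie@channels)) {
    arr <- movie@channels[[ch]] / scale
    for (f in seq_len(dim(arr)[3])) pages[[length(pages) + 1L]] <- arr[, , f]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(schema = "TipKineticsMovie v1",
               channels = names(movie@channels),
               n_frames = dim(movie@channels[[1]])[3],
               shape = dim(movie@channels[[1]])[1:2],
               pixel_size_nm = movie@pixelSize,
               frame_interval_s = movie@frameInterval,
               scale = scale,
               metadata = movie@metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeMovie
#' @export
readMovie <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("movie sidecar not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$schema, "TipKineticsMovie v1"))
    stop("unknown movie schema: ", meta$schema)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  nch <- length(meta$channels)
  nf <- meta$n_frames
  if (length(pages) != nch * nf)
    stop("movie page mismatch: expected ", nch * nf, " pages (",
         nch, " channels x ", nf, " frames), found ", length(pages))
  chans <- vector("list", nch)
  for (c in seq_len(nch)) {
    arr <- array(0, dim = c(meta$shape[1], meta$shape[2], nf))
    for (f in seq_len(nf)) arr[, , f] <- pages[[(c - 1L) * nf + f]]
    chans[[c]] <- arr * meta$scale
  }
  names(chans) <- meta$channels
  movieStack(chans, meta$pixel_size_nm, meta$frame_interval_s,
             metadata = as.list(meta$metadata))
}

#' Polyline region of interest for kymograph extraction
#'
#' @param x,y vertex coordinates, 0-based pixel units (a coordinate of 0 is
#'   the centre of the first pixel).
#' @param width perpendicular averaging width in pixels (odd, >= 1).
#' @return a \code{LineROI} (list with class attribute).
#' @export
lineROI <- function(x, y, width = 1L) {
  if (length(x) < 2L || length(x) != length(y))
    stop("a LineROI needs >= 2 (x, y) vertices")
  if (width < 1L) stop("width must be >= 1")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 width = as.integer(width)), class = "LineROI")
}

## bilinear interpolation on one frame, 0-based pixel-centre coordinates
.bilinear <- function(frame, x, y) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (any(x < 0 | x > nc - 1 | y < 0 | y > nr - 1))
    stop("ROI sample outside the image field")
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- frame[cbind(y0 + 1, x0 + 1)]
  i01 <- frame[cbind(y0 + 1, x0 + 2)]
  i10 <- frame[cbind(y0 + 2, x0 + 1)]
  i11 <- frame[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Build a kymograph by sampling a movie along a polyline
#'
#' Every frame is sampled along the polyline at one-pixel arc-length steps
#' (linear interpolation between pixels, mean over \code{width} perpendicular
#' offsets).  The axial origin is the first vertex; column j corresponds to
#' an arc length of j - 1 pixels from it.
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param roi a \code{\link{lineROI}}.
#' @param channels channels to extract (default: all).
#' @return a \linkS4class{Kymograph}.
#' @export
buildKymograph <- function(movie, roi, channels = channelNames(movie)) {
  stopifnot(is(movie, "MovieStack"), inherits(roi, "LineROI"))
  segLen <- sqrt(diff(roi$x)^2 + diff(roi$y)^2)
  total <- sum(segLen)
  s <- seq(0, total, by = 1)
  cum <- c(0, cumsum(segLen))
  seg <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
              length(segLen))
  f <- (s - cum[seg]) / segLen[seg]
  xs <- roi$x[seg] + f * diff(roi$x)[seg]
  ys <- roi$y[seg] + f * diff(roi$y)[seg]
  ## unit normals per sample (from the segment direction)
  ux <- diff(roi$x)[seg] / segLen[seg]
  uy <- diff(roi$y)[seg] / segLen[seg]
  offs <- seq_len(roi$width) - (roi$width + 1) / 2
  nf <- nFrames(movie)
  out <- lapply(channels, function(ch) {
    arr <- getChannel(movie, ch)
    m <- matrix(0, nf, length(s))
    for (fr in seq_len(nf)) {
      acc <- 0
      for (o in offs)
        acc <- acc + .bilinear(arr[, , fr], xs - o * uy, ys + o * ux)
      m[fr, ] <- acc / length(offs)
    }
    m
  })
  names(out) <- channels
  new("Kymograph", channels = out, pixelSize = movie@pixelSize,
      frameInterval = movie@frameInterval,
      axialOrigin = c(roi$x[1], roi$y[1]),
      metadata = list(width = roi$width))
}

#' Extract one frame's axial intensity profile from a kymograph
#'
#' @param kymo a \linkS4class{Kymograph}.
#' @param channel channel role.
#' @param frame 1-based frame index.
#' @return data.frame with \code{pos_nm} (axial position from the ROI
#'   origin) and \code{intensity}.
#' @export
kymographProfile <- function(kymo, channel, frame) {
  m <- getChannel(kymo, channel)
  if (frame < 1 || frame > nrow(m)) stop("frame out of range")
  data.frame(pos_nm = (seq_len(ncol(m)) - 1) * kymo@pixelSize,
             intensity = m[frame, ])
}

#' Write / read an event table as versioned CSV
#'
#' The first line is a schema comment; unknown schema versions are
#' rejected.  The round trip is lossless for all columns.
#'
#' @param events data.frame of event records.
#' @param path CSV path.
#' @return \code{readEventTable}: the data.frame.
#' @export
writeEventTable <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", EVENT_TABLE_SCHEMA), con)
  write.csv(events, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# "))
    stop("missing schema line in ", path)
  ver <- sub("^# ", "", first)
  if (!identical(ver, EVENT_TABLE_SCHEMA))
    stop("unknown event-table schema: '", ver, "' (expected '",
         EVENT_TABLE_SCHEMA, "')")
  df <- tryCatch(read.csv(path, comment.char = "#"),
                 error = function(e) stop("malformed event table: ",
                                          conditionMessage(e)))
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop("malformed event-table row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  df
}

#' Write / read a SimulationConfig as YAML
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param path YAML path.
#' @return \code{readConfig}: a \linkS4class{SimulationConfig}.
#' @export
writeConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  yaml::write_yaml(list(
    pixel_size_nm = config@pixelSize,
    frame_interval_s = config@frameInterval,
    exposure_s = config@exposure,
    n_frames = config@nFrames,
    image_shape = config@imageShape,
    psf_sigma_nm = as.list(config@psfSigma),
    background = config@background,
    shot_noise_scale = config@shotNoiseScale,
    read_noise_sd = config@readNoiseSD,
    seed = config@seed
  ), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  simulationConfig(
    pixelSize = y$pixel_size_nm,
    frameInterval = y$frame_interval_s,
    exposure = y$exposure_s,
    nFrames = y$n_frames,
    imageShape = unlist(y$image_shape),
    psfSigma = unlist(y$psf_sigma_nm),
    background = y$background,
    shotNoiseScale = y$shot_noise_scale,
    readNoiseSD = y$read_noise_sd,
    seed = y$seed
  )
}
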