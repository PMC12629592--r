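## Time-projection intensity quantification on stabilized microtubules:
## lattice-class comparisons (GTPgammaS vs GDP) and end-vs-lattice ratios
## on GMPCPP microtubules.

#' Sum-projection of a movie channel over a frame window
#'
#' Exact per-pixel sum of the first \code{nFrames} frames.
#'
#' @param stack a \linkS4class{MovieStack}.
#' @param channel channel role.
#' @param nFramesUsed frames to sum (default: all); an error if the stack
#'   is shorter.
#' @return list with \code{pixels} (matrix), \code{n_frames},
#'   \code{frame_interval_s}, \code{pixel_size_nm}.
#' @export
sumProjection <- function(stack, channel = channelNames(stack)[1],
                          nFramesUsed = NULL) {
  arr <- getChannel(stack, channel)
  total <- dim(arr)[3]
  if (is.null(nFramesUsed)) nFramesUsed <- total
  if (nFramesUsed > total)
    stop("requested ", nFramesUsed, " frames but the stack has ", total)
  px <- if (nFramesUsed == 1L) arr[, , 1]
        else apply(arr[, , seq_len(nFramesUsed), drop = FALSE], c(1, 2), sum)
  list(pixels = px, n_frames = nFramesUsed,
       frame_interval_s = frameInterval(stack),
       pixel_size_nm = pixelSize(stack))
}

## mean projection intensity along a polyline ROI (1-px steps, bilinear)
.roiMean <- function(pixels, roi) {
  segLen <- sqrt(diff(roi$x)^2 + diff(roi$y)^2)
  s <- seq(0, sum(segLen), by = 1)
  cum <- c(0, cumsum(segLen))
  seg <- pmin(findInterval(s, cum, rightmost.closed = TRUE), length(segLen))
  f <- (s - cum[seg]) / segLen[seg]
  xs <- roi$x[seg] + f * diff(roi$x)[seg]
  ys <- roi$y[seg] + f * diff(roi$y)[seg]
  mean(.bilinear(pixels, xs, ys))
}

#' Background-subtracted mean microtubule intensity per micron
#'
#' Mean intensity along the microtubule ROI minus the mean of the
#' (disjoint) background ROI, divided by the ROI length in microns.
#'
#' @param projection list from \code{\link{sumProjection}}.
#' @param roi microtubule \code{\link{lineROI}}.
#' @param backgroundRoi off-structure \code{\link{lineROI}}; must not
#'   intersect \code{roi}.
#' @param latticeClass label (e.g. \code{"GTPgammaS"}, \code{"GDP"},
#'   \code{"GMPCPP"}).
#' @return list with \code{intensity_per_um}, \code{length_um},
#'   \code{lattice_class}, \code{background}.
#' @export
microtubuleMeanIntensity <- function(projection, roi, backgroundRoi,
                                     latticeClass = NA_character_) {
  ## disjointness check on 1-px-rounded sample points
  pts <- function(r) {
    segLen <- sqrt(diff(r$x)^2 + diff(r$y)^2)
    s <- seq(0, sum(segLen), by = 1)
    cum <- c(0, cumsum(segLen))
    seg <- pmin(findInterval(s, cum, rightmost.closed = TRUE), length(segLen))
    f <- (s - cum[seg]) / segLen[seg]
    unique(paste(round(r$x[seg] + f * diff(r$x)[seg]),
                 round(r$y[seg] + f * diff(r$y)[seg])))
  }
  if (length(intersect(pts(roi), pts(backgroundRoi))))
    stop("microtubule and background ROIs overlap")
  bg <- .roiMean(projection$pixels, backgroundRoi)
  m <- .roiMean(projection$pixels, roi) - bg
  lenUm <- sum(sqrt(diff(roi$x)^2 + diff(roi$y)^2)) *
    projection$pixel_size_nm / 1000
  if (lenUm <= 0) stop("zero-length microtubule ROI")
  list(intensity_per_um = m / lenUm, length_um = lenUm,
       lattice_class = latticeClass, background = bg)
}

#' Paired lattice-class intensity ratio per flow cell
#'
#' Within each flow cell the ratio of class-A to class-B mean intensities
#' is computed; cells missing a class are skipped (and counted).  The
#' population of per-cell ratios is summarised as mean +/- SEM with a
#' one-sample t test against ratio 1.
#'
#' @param intensities data.frame with \code{cell}, \code{lattice_class},
#'   \code{intensity_per_um}.
#' @param classA,classB lattice-class labels (ratio = A / B).
#' @return list with \code{ratios}, \code{mean}, \code{sem}, \code{n},
#'   \code{p_value} (t test vs 1), \code{n_skipped}.
#' @export
pairedConditionRatio <- function(intensities, classA, classB) {
  cells <- unique(intensities$cell)
  ratios <- numeric(); skipped <- 0L
  for (cl in cells) {
    sub <- intensities[intensities$cell == cl, ]
    a <- sub$intensity_per_um[sub$lattice_class == classA]
    b <- sub$intensity_per_um[sub$lattice_class == classB]
    if (!length(a) || !length(b)) { skipped <- skipped + 1L; next }
    ratios <- c(ratios, mean(a) / mean(b))
  }
  if (!length(ratios)) stop("no flow cell contains both classes")
  p <- if (length(ratios) >= 2L && sd(ratios) > 0)
    stats::t.test(ratios, mu = 1)$p.value else NA_real_
  list(ratios = ratios, mean = mean(ratios),
       sem = if (length(ratios) > 1L) sd(ratios) / sqrt(length(ratios))
             else NA_real_,
       n = length(ratios), p_value = p, n_skipped = skipped)
}

#' End-to-lattice binding-intensity ratio on a stabilized microtubule
#'
#' The microtubule edge is located with the erfc end model on the
#' structure-channel profile; the end window is exactly 3 pixels anchored
#' at the edge midpoint — extending toward the tip by default
#' (\code{direction = "tipward"}) or into the lattice
#' (\code{"latticeward"}) — and the lattice value is the interior mean
#' excluding 3-pixel windows at both ends.
#'
#' @param profilePos_nm axial positions, nm.
#' @param molIntensity molecule-channel intensities along the microtubule.
#' @param mtIntensity structure-channel intensities (for the edge fit).
#' @param pixelSize_nm nm per pixel.
#' @param direction window orientation from the edge midpoint.
#' @param psfGuess edge-fit sigma start, nm.
#' @return list with \code{end_intensity}, \code{lattice_intensity},
#'   \code{ratio}, \code{edge_pos_nm}; microtubules shorter than 10 pixels
#'   are rejected with an error.
#' @export
endLatticeRatio <- function(profilePos_nm, molIntensity, mtIntensity,
                            pixelSize_nm,
                            direction = c("tipward", "latticeward"),
                            psfGuess = 120) {
  direction <- match.arg(direction)
  if (length(profilePos_nm) < 10L)
    stop("microtubule shorter than 10 pixels; skipped")
  endFit <- fitEndProfile(profilePos_nm, mtIntensity, psfGuess = psfGuess)
  if (endFit$flagged) stop("end edge could not be resolved")
  mid <- endFit$edge_pos_nm
  w <- 3 * pixelSize_nm
  win <- if (direction == "tipward") c(mid, mid + w) else c(mid - w, mid)
  inEnd <- profilePos_nm >= win[1] & profilePos_nm <= win[2]
  if (sum(inEnd) < 1L) stop("end window holds no samples")
  ## interior: exclude 3-pixel windows at both extremities of the lattice
  lo <- min(profilePos_nm) + w
  hi <- mid - w
  inLat <- profilePos_nm >= lo & profilePos_nm <= hi
  if (sum(inLat) < 1L) stop("no interior lattice samples")
  e <- mean(molIntensity[inEnd])
  l <- mean(molIntensity[inLat])
  list(end_intensity = e, lattice_intensity = l, ratio = e / l,
       edge_pos_nm = mid)
}
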