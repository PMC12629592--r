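## Sub-pixel localization: microtubule end edges (erfc model), molecule
## peaks (Gaussian), tip-relative event positions, binding-region
## distributions (Gaussian / exponentially modified Gaussian) with FWHM,
## two-color distances, PSF characterization and precision deconvolution.

FWHM_FACTOR <- 2 * sqrt(2 * log(2))   # FWHM = 2.3548... * sigma

#' Fit the microtubule end edge with a PSF-convolved step (erfc) model
#'
#' The lattice is a Gaussian wall and the end a half-Gaussian: their sum is
#' the error-function edge \deqn{I(x) = bg + A \,\Phi((x_e - x)/\sigma)}
#' (equivalently an erfc profile), whose centre \eqn{x_e} — the half-maximum
#' point and the peak of the underlying half-Gaussian — is the end
#' reference.  The model assumes a plus end pointing toward increasing x;
#' pass \code{mirror = TRUE} for the opposite orientation.
#'
#' Initialisation: background = profile minimum, amplitude = max - min,
#' edge at the half-maximum crossing; bounded Levenberg-Marquardt least
#' squares.
#'
#' @param pos_nm axial positions, nm, strictly increasing, >= 8 samples.
#' @param intensity intensities (A.U.).
#' @param psfGuess starting value for the edge sigma, nm.
#' @param mirror logical; TRUE if the plus end points toward decreasing x.
#' @param weighting \code{"poisson"} (default) applies inverse-variance
#'   weights 1/I for shot-noise-limited intensities, which removes the
#'   small edge bias that unweighted least squares picks up from the
#'   brighter lattice side; \code{"none"} is ordinary least squares.
#' @return list with \code{edge_pos_nm}, \code{sigma_nm}, \code{amplitude},
#'   \code{background}, \code{residual_norm}, \code{flagged} (TRUE when the
#'   fit failed or the edge sits at the span boundary; flagged fits are
#'   excluded downstream).
#' @export
fitEndProfile <- function(pos_nm, intensity, psfGuess = 120,
                          mirror = FALSE,
                          weighting = c("poisson", "none")) {
  weighting <- match.arg(weighting)
  if (length(pos_nm) < 8L || any(diff(pos_nm) <= 0))
    stop("profile needs >= 8 strictly increasing positions")
  x <- if (mirror) -rev(pos_nm) else pos_nm
  y <- if (mirror) rev(intensity) else intensity
  bg0 <- min(y); A0 <- max(y) - min(y)
  half <- bg0 + A0 / 2
  above <- which(y >= half)
  xe0 <- if (length(above)) x[max(above)] else mean(range(x))
  ## window around the distal-most falling edge, so that a profile that
  ## also contains the opposite microtubule end (a rising edge) does not
  ## distort the monotone edge model
  win <- which(x >= xe0 - 8 * psfGuess & x <= xe0 + 8 * psfGuess)
  if (length(win) >= 8L) {
    x <- x[win]; y <- y[win]
    bg0 <- min(y); A0 <- max(y) - min(y)
  }
  span <- range(x)
  tryFit <- function(start, weighted) tryCatch({
    args <- list(
      y ~ bg + A * pnorm((xe - x) / sigma),
      start = start,
      lower = c(-Inf, 0, span[1], 1),
      upper = c(Inf, Inf, span[2], diff(span)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (weighted) args$weights <- 1 / pmax(y, 1)
    do.call(minpack.lm::nlsLM, args)
  }, error = function(e) NULL)
  weighted <- weighting == "poisson"
  start1 <- list(bg = bg0, A = A0, xe = xe0, sigma = psfGuess)
  start2 <- list(bg = bg0 - 0.01 * A0, A = 1.05 * A0,
                 xe = min(max(xe0 + 0.3 * psfGuess, span[1]), span[2]),
                 sigma = 1.3 * psfGuess)
  fit <- tryFit(start1, weighted)
  ## an exactly-solvable (noise-free) profile defeats the weighted path
  ## with a zero-residual singular gradient; fall back progressively
  if (is.null(fit)) fit <- tryFit(start2, weighted)
  if (is.null(fit) && weighted) fit <- tryFit(start1, FALSE)
  if (is.null(fit) && weighted) fit <- tryFit(start2, FALSE)
  if (is.null(fit)) {
    return(list(edge_pos_nm = NA_real_, sigma_nm = NA_real_,
                amplitude = NA_real_, background = NA_real_,
                residual_norm = NA_real_, flagged = TRUE))
  }
  p <- coef(fit)
  xe <- unname(p["xe"])
  tol <- 1e-6 * diff(span)
  atEdge <- xe <= span[1] + tol || xe >= span[2] - tol
  edge <- if (mirror) -xe else xe
  list(edge_pos_nm = unname(edge), sigma_nm = unname(p["sigma"]),
       amplitude = unname(p["A"]), background = unname(p["bg"]),
       residual_norm = sqrt(sum(residuals(fit)^2)),
       flagged = atEdge)
}

#' Fit a single-molecule intensity peak with a Gaussian + background
#'
#' @param pos_nm axial positions, nm.
#' @param intensity intensities (A.U.).
#' @param ambiguityRatio a second local maximum above this fraction of the
#'   dominant one raises the ambiguous-peak flag.
#' @return list with \code{center_nm}, \code{sigma_nm}, \code{amplitude},
#'   \code{background}, \code{residual_norm}, \code{flagged},
#'   \code{flag_reason}.
#' @export
fitMoleculePeak <- function(pos_nm, intensity, ambiguityRatio = 0.8) {
  if (length(pos_nm) < 5L) stop("profile too short for a peak fit")
  y <- intensity
  bg0 <- min(y); A0 <- max(y) - bg0
  flagReason <- ""
  if (diff(range(y)) <= .Machine$double.eps * max(abs(y), 1))
    return(list(center_nm = NA_real_, sigma_nm = NA_real_,
                amplitude = NA_real_, background = NA_real_,
                residual_norm = NA_real_, flagged = TRUE,
                flag_reason = "flat profile"))
  ## interior local maxima for ambiguity detection
  n <- length(y)
  isMax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
             FALSE)
  peaks <- sort(y[isMax] - bg0, decreasing = TRUE)
  if (length(peaks) >= 2L && peaks[2] > ambiguityRatio * peaks[1])
    flagReason <- "ambiguous peak"
  mu0 <- pos_nm[which.max(y)]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bg + A * exp(-(pos_nm - mu)^2 / (2 * sigma^2)),
      start = list(bg = bg0, A = A0, mu = mu0,
                   sigma = diff(range(pos_nm)) / 8),
      lower = c(-Inf, 0, min(pos_nm), 1),
      upper = c(Inf, Inf, max(pos_nm), diff(range(pos_nm))),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), error = function(e) NULL)
  if (is.null(fit))
    return(list(center_nm = NA_real_, sigma_nm = NA_real_,
                amplitude = NA_real_, background = NA_real_,
                residual_norm = NA_real_, flagged = TRUE,
                flag_reason = "fit failure"))
  p <- coef(fit)
  list(center_nm = unname(p["mu"]), sigma_nm = unname(p["sigma"]),
       amplitude = unname(p["A"]), background = unname(p["bg"]),
       residual_norm = sqrt(sum(residuals(fit)^2)),
       flagged = nzchar(flagReason), flag_reason = flagReason)
}

#' Tip-relative position of one binding event over its dwell
#'
#' Per frame, the relative position is peak centre minus edge position
#' (distal positive); the event position is the arithmetic mean over the
#' dwell.  Flagged frames are dropped; fewer than 2 valid frames (the
#' 200 ms detection floor at 100 ms/frame) rejects the event.
#'
#' @param endFits list of \code{\link{fitEndProfile}} results, one per frame.
#' @param peakFits list of \code{\link{fitMoleculePeak}} results, matched by
#'   index.
#' @return list with \code{rel_pos_nm} (per valid frame),
#'   \code{mean_pos_nm}, \code{n_frames}, \code{rejected}.
#' @export
localizeEvent <- function(endFits, peakFits) {
  if (length(endFits) != length(peakFits))
    stop("endFits and peakFits must be matched per frame")
  ok <- !vapply(endFits, `[[`, TRUE, "flagged") &
        !vapply(peakFits, `[[`, TRUE, "flagged")
  dx <- vapply(peakFits, `[[`, 1, "center_nm")[ok] -
        vapply(endFits, `[[`, 1, "edge_pos_nm")[ok]
  if (sum(ok) < 2L)
    return(list(rel_pos_nm = dx, mean_pos_nm = NA_real_,
                n_frames = sum(ok), rejected = TRUE))
  list(rel_pos_nm = dx, mean_pos_nm = mean(dx), n_frames = sum(ok),
       rejected = FALSE)
}

#' Exponentially modified Gaussian density
#'
#' With \code{tail = "positive"} the exponential tail extends toward +x;
#' \code{"negative"} mirrors it (the comet-like shape of an EB-cap
#' distribution decaying toward the lattice).
#'
#' @param x evaluation points.
#' @param mu,sigma Gaussian component mean and SD.
#' @param lambda exponential decay rate (1/nm), > 0.
#' @param tail direction of the exponential tail.
#' @return density values.
#' @export
emgDensity <- function(x, mu, sigma, lambda,
                       tail = c("positive", "negative")) {
  tail <- match.arg(tail)
  z <- if (tail == "positive") x else -x
  m <- if (tail == "positive") mu else -mu
  ## log-scale erfc for numerical stability
  arg <- (m + lambda * sigma^2 - z) / (sqrt(2) * sigma)
  logerfc <- pnorm(arg * sqrt(2), lower.tail = FALSE, log.p = TRUE) + log(2)
  exp(log(lambda / 2) + (lambda / 2) * (2 * m + lambda * sigma^2 - 2 * z) +
        logerfc)
}

## numeric FWHM of a unimodal density by dense grid + root refinement
.numericFWHM <- function(f, lower, upper) {
  g <- seq(lower, upper, length.out = 20001L)
  v <- f(g)
  imax <- which.max(v)
  half <- v[imax] / 2
  lo <- g[max(which(v[1:imax] <= half))]
  lo <- uniroot(function(x) f(x) - half, c(lo, g[imax]),
                tol = 1e-6)$root
  hiIdx <- imax - 1L + min(which(v[imax:length(v)] <= half))
  hi <- uniroot(function(x) f(x) - half, c(g[imax], g[hiIdx]),
                tol = 1e-6)$root
  hi - lo
}

#' Fit a binding-position distribution and report its FWHM
#'
#' Event positions are binned (probability-normalised histogram) and the
#' chosen model is least-squares fitted to the bin probabilities, matching
#' the probability-distribution fits used for binding-region estimation.
#' For the Gaussian model FWHM = 2*sqrt(2*ln 2)*sigma exactly and the
#' binding-region bounds [mu - FWHM/2, mu + FWHM/2] are exported for region
#' classification; for the EMG model the FWHM is computed numerically.
#'
#' @param positions event positions, nm (>= 30 for a stable fit).
#' @param model \code{"gaussian"} or \code{"emg"}.
#' @param binWidth histogram bin width, nm.
#' @param tail EMG tail direction (see \code{\link{emgDensity}}).
#' @return list with \code{model}, \code{mu}, \code{sigma} (and
#'   \code{lambda} for EMG), \code{fwhm_nm}, \code{bounds_nm} (Gaussian
#'   only), \code{n}, \code{bin_width_nm}.
#' @export
fitPositionDistribution <- function(positions, model = c("gaussian", "emg"),
                                    binWidth = 20,
                                    tail = c("negative", "positive")) {
  model <- match.arg(model)
  tail <- match.arg(tail)
  n <- length(positions)
  if (n < 30L) stop("need >= 30 positions for a stable distribution fit")
  edges <- seq(floor(min(positions) / binWidth) * binWidth,
               ceiling(max(positions) / binWidth) * binWidth + binWidth,
               by = binWidth)
  h <- graphics::hist(positions, breaks = edges, plot = FALSE)
  xb <- h$mids
  pb <- h$counts / n
  mu0 <- mean(positions); s0 <- sd(positions)
  if (s0 < binWidth / 10) stop("degenerate position distribution")
  if (model == "gaussian") {
    fit <- minpack.lm::nlsLM(
      pb ~ a * exp(-(xb - mu)^2 / (2 * sigma^2)),
      start = list(a = max(pb), mu = mu0, sigma = s0),
      lower = c(0, min(xb), binWidth / 10),
      upper = c(1, max(xb), diff(range(xb))))
    p <- coef(fit)
    if (p["sigma"] >= diff(range(xb)) * 0.999)
      stop("degenerate Gaussian fit: sigma at the span")
    fwhm <- FWHM_FACTOR * unname(p["sigma"])
    list(model = "gaussian", mu = unname(p["mu"]),
         sigma = unname(p["sigma"]), fwhm_nm = fwhm,
         bounds_nm = unname(p["mu"]) + c(-1, 1) * fwhm / 2,
         n = n, bin_width_nm = binWidth)
  } else {
    sk <- mean(((positions - mu0) / s0)^3)
    lam0 <- 1 / max(binWidth / 2, s0 * abs(sk)^(1 / 3))
    fit <- minpack.lm::nlsLM(
      pb ~ a * emgDensity(xb, mu, sigma, lambda, tail = tail),
      start = list(a = n * binWidth / n, mu = mu0, sigma = s0 / 2,
                   lambda = lam0),
      lower = c(0, min(xb) - diff(range(xb)), binWidth / 10, 1e-5),
      upper = c(Inf, max(xb) + diff(range(xb)), diff(range(xb)), 1),
      control = minpack.lm::nls.lm.control(maxiter = 400))
    p <- coef(fit)
    f <- function(x) emgDensity(x, p["mu"], p["sigma"], p["lambda"],
                                tail = tail)
    span <- range(positions) + c(-4, 4) * s0
    fwhm <- .numericFWHM(f, span[1], span[2])
    list(model = "emg", mu = unname(p["mu"]), sigma = unname(p["sigma"]),
         lambda = unname(p["lambda"]), tail = tail, fwhm_nm = fwhm,
         n = n, bin_width_nm = binWidth)
  }
}

#' Two-color axial distance between co-bound molecules
#'
#' Per frame the distance is centre_B minus centre_A (channel A is the
#' origin, plus any supplied registration offset); each event contributes
#' the mean over the frames of B's dwell.  The modal distance is the mean
#' of a Gaussian fitted to the binned probability distribution of event
#' distances.
#'
#' @param events list; each element has numeric vectors \code{a} and
#'   \code{b} of per-frame peak centres (nm) in matched frames.
#' @param registrationOffset channel B-to-A registration offset, nm.
#' @param binWidth histogram bin width for the modal estimate, nm.
#' @return list with \code{event_distance_nm}, \code{mode_nm},
#'   \code{mean_nm}, \code{fraction_positive}, \code{fit} (the Gaussian
#'   distribution fit), \code{n}.
#' @export
twoColorDistance <- function(events, registrationOffset = 0, binWidth = 20) {
  d <- vapply(events, function(e) {
    if (length(e$a) != length(e$b))
      stop("channels must be fitted in the same frames")
    mean(e$b - e$a) + registrationOffset
  }, 1)
  fit <- if (length(d) >= 30L && sd(d) > 0)
    tryCatch(fitPositionDistribution(d, "gaussian", binWidth = binWidth),
             error = function(e) NULL) else NULL
  list(event_distance_nm = d,
       mode_nm = if (!is.null(fit)) fit$mu else NA_real_,
       mean_nm = mean(d),
       fraction_positive = mean(d > 0),
       fit = fit, n = length(d))
}

#' Estimate the system PSF width from a bead stack
#'
#' Beads are detected as local maxima of the time-averaged frame; each
#' bead's width is the mean of Gaussian fits to its x and y marginal
#' profiles, corrected for pixel-box integration (the fitted width of a
#' pixel-integrated Gaussian carries an extra px^2/12 in quadrature), and
#' the per-channel estimate is the median across beads.
#'
#' @param stack a \linkS4class{MovieStack} of stationary beads.
#' @param window half-width of the fitting window, pixels.
#' @param minBeads fewer detected beads than this raises a warning (the
#'   estimate is still returned).
#' @return named numeric: sigma_PSF per channel, nm; attribute
#'   \code{per_bead} holds the per-bead widths per channel.
#' @export
estimatePsfSigma <- function(stack, window = 6L, minBeads = 10L) {
  stopifnot(is(stack, "MovieStack"))
  px <- pixelSize(stack)
  perBead <- lapply(channelNames(stack), function(ch) {
    arr <- getChannel(stack, ch)
    avg <- apply(arr, c(1, 2), mean)
    bg <- median(avg)
    thr <- bg + 8 * mad(as.vector(avg))
    nr <- nrow(avg); nc <- ncol(avg)
    cand <- which(avg > thr, arr.ind = TRUE)
    cand <- cand[order(avg[cand], decreasing = TRUE), , drop = FALSE]
    used <- matrix(FALSE, nr, nc)
    sigmas <- numeric()
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1]; c <- cand[i, 2]
      if (used[r, c]) next
      if (r <= window || r > nr - window || c <= window || c > nc - window)
        next
      win <- avg[(r - window):(r + window), (c - window):(c + window)]
      if (max(win) > avg[r, c]) next    # not the local maximum
      used[max(1, r - 2 * window):min(nr, r + 2 * window),
           max(1, c - 2 * window):min(nc, c + 2 * window)] <- TRUE
      ## crowding guard: a second peak in the window would inflate the
      ## width fit, so skip beads with close neighbours
      ctr <- window + 1L
      amp <- win[ctr, ctr] - bg
      rim <- win
      rim[pmax(1, ctr - 2):pmin(2 * window + 1, ctr + 2),
          pmax(1, ctr - 2):pmin(2 * window + 1, ctr + 2)] <- bg
      if (max(rim) - bg > 0.5 * amp) next
      idx <- (-window):window
      sx <- tryCatch({
        prof <- colSums(win - bg)
        f <- minpack.lm::nlsLM(prof ~ A * exp(-(idx - m)^2 / (2 * s^2)) + b,
                               start = list(A = max(prof), m = 0,
                                            s = 1.2, b = 0))
        abs(coef(f)["s"])
      }, error = function(e) NA_real_)
      sy <- tryCatch({
        prof <- rowSums(win - bg)
        f <- minpack.lm::nlsLM(prof ~ A * exp(-(idx - m)^2 / (2 * s^2)) + b,
                               start = list(A = max(prof), m = 0,
                                            s = 1.2, b = 0))
        abs(coef(f)["s"])
      }, error = function(e) NA_real_)
      s <- mean(c(sx, sy), na.rm = TRUE)
      if (is.finite(s)) {
        s2 <- (s * px)^2 - px^2 / 12      # remove pixel-box broadening
        if (s2 > 0) sigmas <- c(sigmas, sqrt(s2))
      }
    }
    if (length(sigmas) < minBeads)
      warning("only ", length(sigmas), " beads detected in channel '", ch,
              "' (recommended >= ", minBeads, ")")
    sigmas
  })
  names(perBead) <- channelNames(stack)
  out <- vapply(perBead, median, 1)
  attr(out, "per_bead") <- perBead
  out
}

#' Deconvolve localization precision from an observed width
#'
#' The observed image width is the quadrature sum of the measurement error
#' and the system PSF width: sigma_I^2 = sigma_O^2 + sigma_PSF^2.  This
#' inverts it exactly: sigma_O = sqrt(sigma_I^2 - sigma_PSF^2).  Records
#' with sigma_I < sigma_PSF are noise-dominated: they return NA and are
#' counted in the \code{n_excluded} attribute.
#'
#' @param sigmaI observed width(s), nm.
#' @param sigmaPSF system PSF width, nm.
#' @return sigma_O, nm (NA where excluded), with attribute
#'   \code{n_excluded}.
#' @examples
#' deconvolvePrecision(121.34, 120)   # ~18 nm
#' @export
deconvolvePrecision <- function(sigmaI, sigmaPSF) {
  bad <- sigmaI < sigmaPSF
  out <- ifelse(bad, NA_real_, sqrt(pmax(sigmaI^2 - sigmaPSF^2, 0)))
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Population localization precision
#'
#' The SD of a Gaussian fitted to the probability distribution of per-event
#' mean measurement errors.
#'
#' @param errors per-event mean measurement errors, nm.
#' @param binWidth histogram bin width, nm.
#' @return precision, nm.
#' @export
populationPrecision <- function(errors, binWidth = NULL) {
  errors <- errors[is.finite(errors)]
  if (is.null(binWidth))
    binWidth <- max(diff(range(errors)) / 15, 1e-6)
  fitPositionDistribution(errors, "gaussian", binWidth = binWidth)$sigma
}
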