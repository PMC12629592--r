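## Ground-truthed synthetic TIRF data: microtubule dynamics, single-molecule
## binding, rendered movies, dwell samples, Brownian trajectories and bead
## stacks.  Every estimator in the package can be exercised against the truth
## these functions record.

#' Simulate microtubule growth and catastrophe truth
#'
#' Each microtubule nucleates at its anchor, grows linearly at
#' \code{growthRate} and undergoes catastrophe after a gamma-distributed
#' lifetime.  Lifetimes longer than the movie are censored at the movie end
#' and flagged, not dropped.  Catastrophe is modelled as instantaneous end
#' disappearance; shrinkage is not rendered because the downstream analysis
#' consumes growth phases and lifetimes only.
#'
#' @param config a \linkS4class{SimulationConfig}; sets the movie duration
#'   used for censoring and the field for anchor placement.
#' @param growthRate growth speed, um/min.
#' @param lifetimeShape,lifetimeScale gamma shape (dimensionless) and scale
#'   (s) of the lifetime distribution; shape 1 gives exponential lifetimes.
#' @param nMicrotubules number of microtubules.
#' @param latticeLength initial (seed) lattice length, nm.
#' @param seed optional integer seed.
#' @return data.frame, one row per microtubule: \code{id}, \code{anchor_x_nm},
#'   \code{anchor_y_nm}, \code{growth_rate_um_min}, \code{lifetime_s} (true),
#'   \code{observed_lifetime_s} (censored at movie end), \code{censored},
#'   \code{lattice_length_nm}.
#' @examples
#' cfg <- simulationConfig(nFrames = 50, seed = 3)
#' mts <- simulateDynamics(cfg, growthRate = 0.8, lifetimeShape = 3,
#'                         lifetimeScale = 107.8, nMicrotubules = 5)
#' @export
simulateDynamics <- function(config, growthRate = 0.8, lifetimeShape = 3,
                             lifetimeScale = 107.8, nMicrotubules = 1L,
                             latticeLength = 4000, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (growthRate < 0) stop("growthRate must be >= 0")
  if (lifetimeShape <= 0 || lifetimeScale <= 0)
    stop("lifetime shape and scale must be > 0")
  if (nMicrotubules < 1) stop("nMicrotubules must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  duration <- config@nFrames * config@frameInterval
  lifetime <- rgamma(nMicrotubules, shape = lifetimeShape,
                     scale = lifetimeScale)
  censored <- lifetime > duration
  shape <- config@imageShape
  ## anchor in nm within the field, leaving room for the seed lattice
  anchor_x <- runif(nMicrotubules, latticeLength + 2 * config@pixelSize,
                    0.5 * shape[2] * config@pixelSize)
  anchor_y <- runif(nMicrotubules, 0.25, 0.75) * shape[1] * config@pixelSize
  data.frame(
    id = seq_len(nMicrotubules),
    anchor_x_nm = anchor_x,
    anchor_y_nm = anchor_y,
    growth_rate_um_min = growthRate,
    lifetime_s = lifetime,
    observed_lifetime_s = pmin(lifetime, duration),
    censored = censored,
    lattice_length_nm = latticeLength
  )
}

#' Microtubule end position at a given time
#'
#' Linear growth from the anchor until catastrophe; NA afterwards
#' (instantaneous disappearance).
#'
#' @param mt one row of the data.frame from \code{\link{simulateDynamics}}.
#' @param t time, s (vectorised).
#' @return end x position(s), nm.
#' @export
endPositionAt <- function(mt, t) {
  v <- mt$growth_rate_um_min * 1000 / 60     # nm/s
  pos <- mt$anchor_x_nm + v * t
  pos[t >= mt$lifetime_s] <- NA_real_
  pos
}

#' Simulate single-molecule binding truth on dynamic microtubules
#'
#' Arrivals in each region are Poisson: rate = kon * C * n_sites, with the
#' end region a fixed window of dimer sites tracking the moving tip and the
#' lattice the seed lattice body.  Dwells are exponential with the region's
#' mean.  Lattice-bound molecules perform 1D Brownian motion in the lab
#' frame (increment variance 2*D*dt per frame); end-bound molecules move
#' with the tip.  Positions are recorded relative to the instantaneous tip,
#' distal positive.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param microtubules data.frame from \code{\link{simulateDynamics}}.
#' @param konEnd,konLattice association rates, s^-1 nM^-1 per tubulin dimer.
#' @param tauEnd,tauLattice mean dwell times, s.
#' @param D lattice diffusion coefficient, um^2/s.
#' @param concentration molecule concentration, nM.
#' @param endRegionLength end-region length, nm (160 nm = 260 dimer sites at
#'   13 protofilaments and 8 nm repeat).
#' @param protofilaments,dimerRepeat lattice geometry (sites per ring, axial
#'   repeat in nm).
#' @param intensityMean,intensitySD per-molecule brightness distribution
#'   (A.U.), Gaussian.
#' @param channel channel role the molecules are rendered into.
#' @param seed optional integer seed.
#' @return list with \code{events} (data.frame: molecule_id, mt_id,
#'   site_class, arrival_time_s, dwell_s, intensity, channel) and
#'   \code{traces} (list of data.frames: time_s, rel_pos_nm — tip-relative,
#'   distal positive — sampled at frame times within the dwell).
#' @export
simulateBinding <- function(config, microtubules,
                            konEnd = 22.6e-6, konLattice = 2.8e-6,
                            tauEnd = 0.75, tauLattice = 0.62,
                            D = 0.023, concentration = 10,
                            endRegionLength = 160,
                            protofilaments = 13L, dimerRepeat = 8,
                            intensityMean = 300, intensitySD = 72.5,
                            channel = "molecule", seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (konEnd < 0 || konLattice < 0 || tauEnd < 0 || tauLattice < 0 || D < 0)
    stop("rates, dwell means and D must be >= 0")
  if (concentration <= 0) stop("concentration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  dt <- config@frameInterval
  duration <- config@nFrames * dt
  nEnd <- siteCount(endRegionLength, protofilaments, dimerRepeat)
  events <- list(); traces <- list(); k <- 0L
  for (i in seq_len(nrow(microtubules))) {
    mt <- microtubules[i, ]
    Tobs <- min(mt$lifetime_s, duration)
    nLat <- siteCount(mt$lattice_length_nm, protofilaments, dimerRepeat)
    for (class in c("end", "lattice")) {
      rate <- if (class == "end") konEnd * concentration * nEnd
              else konLattice * concentration * nLat
      nArr <- rpois(1L, rate * Tobs)
      if (nArr == 0L) next
      t0 <- sort(runif(nArr, 0, Tobs))
      tau <- if (class == "end") tauEnd else tauLattice
      dwell <- rexp(nArr, rate = 1 / tau)
      for (j in seq_len(nArr)) {
        k <- k + 1L
        tEnd <- min(t0[j] + dwell[j], Tobs)
        fr0 <- ceiling(t0[j] / dt) * dt
        frames <- if (fr0 > tEnd) t0[j] else seq(fr0, tEnd, by = dt)
        if (class == "end") {
          ## stationary in the tip frame within the end window
          rel0 <- rnorm(1L, 0, endRegionLength / (2 * sqrt(2 * log(2))))
          rel <- rep(rel0, length(frames))
        } else {
          rel0 <- -runif(1L, endRegionLength / 2, mt$lattice_length_nm)
          ## Brownian in the lab frame; the tip advances under the molecule
          v <- mt$growth_rate_um_min * 1000 / 60
          steps <- rnorm(length(frames) - 1L, 0, sqrt(2 * D * dt) * 1000)
          lab <- cumsum(c(rel0, steps))
          rel <- lab - v * (frames - frames[1])
        }
        events[[k]] <- data.frame(
          molecule_id = k, mt_id = mt$id, site_class = class,
          arrival_time_s = t0[j], dwell_s = dwell[j],
          intensity = rnorm(1L, intensityMean, intensitySD),
          channel = channel
        )
        traces[[k]] <- data.frame(time_s = frames, rel_pos_nm = rel)
      }
    }
  }
  if (k == 0L)
    return(list(events = data.frame(molecule_id = integer(), mt_id = integer(),
                                    site_class = character(),
                                    arrival_time_s = numeric(),
                                    dwell_s = numeric(), intensity = numeric(),
                                    channel = character()),
                traces = list()))
  list(events = do.call(rbind, events), traces = traces)
}

## pixel-integrated 1D Gaussian: integral of N(mu, sigma) over each pixel
## [edges[i], edges[i+1]]; sums to 1 over the whole line.
.pixGauss <- function(edges, mu, sigma) {
  p <- pnorm(edges, mean = mu, sd = sigma)
  diff(p)
}

## pixel integral of the erf edge profile of a line segment [xs, xe]
## convolved with a Gaussian PSF, per unit line density.  Uses the
## antiderivative  int Phi(u) du = u*Phi(u) + phi(u)  so that the total over
## the field equals (xe - xs) exactly (photon conservation).
.pixEdge <- function(edges, xs, xe, sigma) {
  F <- function(x, m) {
    u <- (x - m) / sigma
    sigma * (u * pnorm(u) + dnorm(u))
  }
  val <- (F(edges, xs) - F(edges, xe))
  diff(val)
}

#' Render a synthetic TIRF movie from simulation truth
#'
#' Microtubules are drawn as PSF-convolved horizontal line sources whose
#' plus end is a half-Gaussian (erf) edge at the instantaneous tip
#' position; molecules are pixel-integrated 2D Gaussian emitters.  Noise is
#' Poisson shot noise on signal plus background (on the photon scale set by
#' \code{shotNoiseScale}) followed by additive Gaussian read noise.  In the
#' noiseless limit each frame sums to \code{background * n_pixels} plus the
#' total emitter brightness in the field (photon conservation).
#'
#' @param config a \linkS4class{SimulationConfig}; \code{config@seed}
#'   makes the output bit-identical across runs.
#' @param microtubules data.frame from \code{\link{simulateDynamics}}.
#' @param binding list from \code{\link{simulateBinding}}, or NULL.
#' @param mtBrightness line brightness, A.U. per um of lattice.
#' @param noise logical; apply shot and read noise.
#' @return a \linkS4class{MovieStack} with channels \code{microtubule} and
#'   (if binding events exist) the binding channel.
#' @export
renderMovie <- function(config, microtubules, binding = NULL,
                        mtBrightness = 2000, noise = TRUE) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  shape <- config@imageShape
  px <- config@pixelSize
  xe_edges <- (0:shape[2]) * px      # pixel edges, nm (0-based pixels)
  ye_edges <- (0:shape[1]) * px
  dt <- config@frameInterval
  chans <- names(config@psfSigma)
  mtChan <- if ("microtubule" %in% chans) "microtubule" else chans[1]
  molChan <- if (!is.null(binding) && nrow(binding$events))
    unique(binding$events$channel) else character()
  roles <- unique(c(mtChan, molChan))
  stacks <- lapply(roles, function(r)
    array(0, dim = c(shape[1], shape[2], config@nFrames)))
  names(stacks) <- roles
  clipped <- 0L
  for (f in seq_len(config@nFrames)) {
    t <- (f - 1L) * dt
    frame_mt <- matrix(0, shape[1], shape[2])
    sigma_mt <- config@psfSigma[[mtChan]]
    for (i in seq_len(nrow(microtubules))) {
      mt <- microtubules[i, ]
      if (t >= mt$lifetime_s) next
      tip <- mt$anchor_x_nm + mt$growth_rate_um_min * 1000 / 60 * t
      xs <- mt$anchor_x_nm - mt$lattice_length_nm
      dens <- mtBrightness / 1000          # A.U. per nm
      ix <- .pixEdge(xe_edges, xs, tip, sigma_mt) * dens
      iy <- .pixGauss(ye_edges, mt$anchor_y_nm, sigma_mt)
      frame_mt <- frame_mt + outer(iy, ix)
    }
    stacks[[mtChan]][, , f] <- frame_mt
    if (length(molChan)) {
      ev <- binding$events
      for (r in molChan) {
        frame_mol <- matrix(0, shape[1], shape[2])
        sigma_mol <- if (r %in% names(config@psfSigma))
          config@psfSigma[[r]] else config@psfSigma[[1]]
        sel <- which(ev$channel == r)
        for (j in sel) {
          tr <- binding$traces[[j]]
          m <- which(abs(tr$time_s - t) < dt / 2)
          if (!length(m)) next
          mt <- microtubules[microtubules$id == ev$mt_id[j], ]
          tip <- mt$anchor_x_nm + mt$growth_rate_um_min * 1000 / 60 * t
          x0 <- tip + tr$rel_pos_nm[m[1]]
          y0 <- mt$anchor_y_nm
          if (x0 < -3 * sigma_mol || x0 > shape[2] * px + 3 * sigma_mol) {
            clipped <- clipped + 1L
            next
          }
          frame_mol <- frame_mol + ev$intensity[j] *
            outer(.pixGauss(ye_edges, y0, sigma_mol),
                  .pixGauss(xe_edges, x0, sigma_mol))
        }
        stacks[[r]][, , f] <- frame_mol
      }
    }
  }
  if (clipped > 0L)
    warning(clipped, " emitter frame(s) outside the field were clipped")
  for (r in roles) {
    sig <- stacks[[r]] + config@background
    if (noise && config@shotNoiseScale > 0) {
      s <- config@shotNoiseScale
      sig <- array(rpois(length(sig), lambda = as.vector(sig) * s) / s,
                   dim = dim(sig))
    }
    if (noise && config@readNoiseSD > 0)
      sig <- sig + array(rnorm(length(sig), 0, config@readNoiseSD),
                         dim = dim(sig))
    stacks[[r]] <- sig
  }
  movieStack(stacks, config@pixelSize, config@frameInterval,
             metadata = list(seed = config@seed, noise = noise))
}

#' Draw exponential dwell-time samples, optionally left-truncated
#'
#' With a detection floor \code{minDwell > 0} the samples are exponential
#' conditioned on exceeding the floor, which by memorylessness is
#' \code{minDwell + Exp(tau)}: the observed mean converges to
#' \code{minDwell + tau}.
#'
#' @param tau mean dwell, s.
#' @param n number of samples.
#' @param minDwell detection floor, s.
#' @param seed optional integer seed.
#' @return numeric vector of dwell times, s.
#' @examples
#' mean(simulateDwellSamples(0.55, 1e4, minDwell = 0.2, seed = 1)) # ~0.75
#' @export
simulateDwellSamples <- function(tau, n, minDwell = 0, seed = NULL) {
  if (tau <= 0) stop("tau must be > 0")
  if (minDwell < 0) stop("minDwell must be >= 0")
  if (n == 0) return(numeric())
  if (!is.null(seed)) set.seed(seed)
  minDwell + rexp(n, rate = 1 / tau)
}

#' Simulate 1D Brownian trajectories on the lattice
#'
#' Positions have independent Gaussian increments of variance
#' \code{2 * D * dt}.  Track lengths below 4 frames are rejected, honouring
#' the 400 ms minimum track length at 100 ms/frame used for diffusion
#' estimation.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param n number of trajectories.
#' @param nFrames frames per trajectory; scalar or vector of length
#'   \code{n}.
#' @param dt frame interval, s.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{track}, \code{frame} (0-based),
#'   \code{time_s}, \code{pos_um}.
#' @export
simulateTrajectories <- function(D, n, nFrames = 20L, dt = 0.1,
                                 seed = NULL) {
  if (D < 0) stop("D must be >= 0")
  if (any(nFrames < 4L))
    stop("nFrames must be >= 4 (minimum track length)")
  if (!is.null(seed)) set.seed(seed)
  nf <- rep_len(as.integer(nFrames), n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    steps <- rnorm(nf[i] - 1L, 0, sqrt(2 * D * dt))
    pos <- cumsum(c(0, steps))
    out[[i]] <- data.frame(track = i, frame = seq_len(nf[i]) - 1L,
                           time_s = (seq_len(nf[i]) - 1L) * dt,
                           pos_um = pos)
  }
  do.call(rbind, out)
}

#' Render a stack of stationary fluorescent beads
#'
#' Beads (nominally 100 nm diameter, far below the diffraction limit) are
#' bright point sources used to characterize the system PSF.  One channel
#' is rendered per entry of \code{config@psfSigma}; the true positions and
#' widths are recorded in the stack metadata.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param nBeads number of beads.
#' @param nFrames frames to render (defaults to \code{config@nFrames}).
#' @param brightness per-bead brightness, A.U. (much brighter than single
#'   molecules).
#' @param noise logical.
#' @return a \linkS4class{MovieStack}; metadata holds \code{bead_x_nm},
#'   \code{bead_y_nm} and \code{psf_sigma}.
#' @export
renderBeadStack <- function(config, nBeads = 20L, nFrames = NULL,
                            brightness = 20000, noise = TRUE) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  if (is.null(nFrames)) nFrames <- config@nFrames
  shape <- config@imageShape
  px <- config@pixelSize
  margin <- 4 * max(config@psfSigma)
  bx <- runif(nBeads, margin, shape[2] * px - margin)
  by <- runif(nBeads, margin, shape[1] * px - margin)
  xe <- (0:shape[2]) * px
  ye <- (0:shape[1]) * px
  stacks <- lapply(names(config@psfSigma), function(ch) {
    sigma <- config@psfSigma[[ch]]
    base <- matrix(0, shape[1], shape[2])
    for (b in seq_len(nBeads))
      base <- base + brightness *
        outer(.pixGauss(ye, by[b], sigma), .pixGauss(xe, bx[b], sigma))
    arr <- array(rep(base + config@background, nFrames),
                 dim = c(shape[1], shape[2], nFrames))
    if (noise && config@shotNoiseScale > 0) {
      s <- config@shotNoiseScale
      arr <- array(rpois(length(arr), as.vector(arr) * s) / s, dim = dim(arr))
    }
    if (noise && config@readNoiseSD > 0)
      arr <- arr + array(rnorm(length(arr), 0, config@readNoiseSD),
                         dim = dim(arr))
    arr
  })
  names(stacks) <- names(config@psfSigma)
  movieStack(stacks, px, config@frameInterval,
             metadata = list(bead_x_nm = bx, bead_y_nm = by,
                             psf_sigma = config@psfSigma,
                             brightness = brightness, seed = config@seed))
}
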