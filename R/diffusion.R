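## Lattice diffusion: MSD estimation, diffusion-coefficient regression,
## scanned length, and the Fick's-law model of 1D diffusive delivery to the
## growing end, with a brute-force walker simulation as an independent
## numerical route.

#' Ensemble mean-squared displacement of 1D trajectories
#'
#' Per trajectory, the time-averaged squared displacement at each lag; the
#' curve is the unweighted ensemble mean across trajectories with SEM over
#' trajectories.  MSD(0) = 0 by construction.
#'
#' @param trajectories data.frame from \code{\link{simulateTrajectories}}
#'   (columns \code{track}, \code{time_s}, \code{pos_um}) or a list of
#'   per-track data.frames.
#' @param maxLag maximum lag in frames; truncated with a warning if it
#'   exceeds the shortest trajectory.
#' @return data.frame: \code{lag} (frames), \code{t_s}, \code{msd_um2},
#'   \code{sem}, \code{n_tracks}.
#' @export
computeMSD <- function(trajectories, maxLag = 10L) {
  if (is.data.frame(trajectories))
    trajectories <- split(trajectories, trajectories$track)
  lens <- vapply(trajectories, nrow, 1L)
  if (any(lens < 4L)) stop("trajectories must have >= 4 frames")
  dt <- diff(trajectories[[1]]$time_s[1:2])
  shortest <- min(lens)
  if (maxLag > shortest - 1L) {
    warning("maxLag truncated to ", shortest - 1L,
            " (shortest trajectory)")
    maxLag <- shortest - 1L
  }
  perLag <- lapply(seq_len(maxLag), function(k) {
    vapply(trajectories, function(tr) {
      x <- tr$pos_um
      n <- length(x)
      if (n <= k) return(NA_real_)
      mean((x[(k + 1):n] - x[1:(n - k)])^2)
    }, 1)
  })
  data.frame(
    lag = seq_len(maxLag),
    t_s = seq_len(maxLag) * dt,
    msd_um2 = vapply(perLag, mean, 1, na.rm = TRUE),
    sem = vapply(perLag, function(v) {
      v <- v[is.finite(v)]
      sd(v) / sqrt(length(v))
    }, 1),
    n_tracks = vapply(perLag, function(v) sum(is.finite(v)), 1L)
  )
}

#' Diffusion coefficient from the MSD curve
#'
#' Unweighted linear regression of MSD on lag time over the first
#' \code{nLags} lags with a free intercept (the intercept absorbs static
#' localization error); D = slope / 2 from <x^2> = 2 D t.
#'
#' @param msd data.frame from \code{\link{computeMSD}}.
#' @param nLags lags used in the regression (>= 2).
#' @return list with \code{D_um2_s}, \code{intercept_um2},
#'   \code{slope_se}, \code{D_se}.
#' @export
fitDiffusionCoefficient <- function(msd, nLags = 4L) {
  use <- msd[seq_len(min(nLags, nrow(msd))), ]
  if (nrow(use) < 2L) stop("need >= 2 usable lags")
  fit <- lm(msd_um2 ~ t_s, data = use)
  sl <- coef(fit)[["t_s"]]
  se <- summary(fit)$coefficients["t_s", "Std. Error"]
  ## propagate the per-lag ensemble SEMs through the least-squares slope
  ## (the residual-based SE is unreliable with few, nearly collinear lags)
  if ("sem" %in% names(use) && all(is.finite(use$sem))) {
    w <- (use$t_s - mean(use$t_s)) / sum((use$t_s - mean(use$t_s))^2)
    se <- sqrt(sum(w^2 * use$sem^2))
  }
  D <- sl / 2
  if (D < 0) {
    warning("negative MSD slope; reporting D = 0")
    D <- 0
  }
  list(D_um2_s = D, intercept_um2 = coef(fit)[[1]],
       slope_se = se, D_se = se / 2)
}

#' Mean length scanned by 1D lattice diffusion during a dwell
#'
#' sqrt(2 * D * tau), in nm.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param tau mean lattice dwell, s.
#' @return scanned length, nm.
#' @examples
#' scannedLength(0.023, 0.6)    # ~166 nm
#' @export
scannedLength <- function(D, tau) {
  if (D < 0 || tau < 0) stop("D and tau must be >= 0")
  sqrt(2 * D * tau) * 1000
}

#' Fick's-law model of diffusive delivery to the growing end
#'
#' Steady-state 1D reaction-diffusion on the lattice with an absorbing end:
#' molecules bind anywhere at kon * C per dimer site, diffuse with
#' coefficient D, and unbind at koff.  The lattice concentration relaxes to
#' \deqn{c_\infty = (k_{on} C / k_{off}) \rho} (site occupancy times linear
#' site density) over the decay length \deqn{x_0 = \sqrt{D / k_{off}}}, and
#' the flux into the end is \deqn{J_0 = D c_\infty / x_0
#' = c_\infty \sqrt{D k_{off}}.}
#'
#' @param D um^2/s.
#' @param konLattice s^-1 nM^-1 per dimer.
#' @param koffLattice s^-1.
#' @param concentration nM.
#' @param siteDensity dimer sites per um of lattice (13 pf x 8 nm repeat
#'   = 1625/um).
#' @return list with \code{c_inf_per_um}, \code{x0_um}, \code{J0_per_s} and
#'   the inputs.
#' @examples
#' fluxModel(0.023, 2.8e-6, 2.8e-6 * 1057e3, 10)$J0_per_s   # ~0.004
#' @export
fluxModel <- function(D, konLattice, koffLattice, concentration,
                      siteDensity = 1625) {
  if (any(c(D, konLattice, koffLattice, concentration, siteDensity) <= 0))
    stop("all flux-model parameters must be > 0")
  cInf <- konLattice * concentration / koffLattice * siteDensity
  x0 <- sqrt(D / koffLattice)
  list(D = D, kon_lattice = konLattice, koff_lattice = koffLattice,
       concentration = concentration, site_density = siteDensity,
       c_inf_per_um = cInf, x0_um = x0, J0_per_s = D * cInf / x0)
}

#' @rdname fluxModel
#' @param model list from \code{fluxModel}.
#' @export
fluxToEnd <- function(model) model$J0_per_s

#' Brute-force walker simulation of the diffusive flux
#'
#' Independent numerical route to the same quantity as
#' \code{\link{fluxModel}}: binding events arrive Poisson-uniformly on a
#' lattice segment [0, L], each molecule performs Brownian steps of
#' variance 2 D dt, detaches after an exponential dwell (rate koff) and is
#' absorbed if it reaches the end at x = 0.  The absorbed fraction times
#' the total binding rate estimates J0.  Because the flux is linear in
#' concentration, simulating many events at once simply improves the
#' Monte-Carlo error.
#'
#' @inheritParams fluxModel
#' @param L simulated lattice length, um (>> x0).
#' @param dt time step, s.
#' @param nEvents number of binding events to simulate.
#' @param seed optional seed.
#' @return list with \code{J0_per_s} (simulated), \code{se} (binomial
#'   Monte-Carlo SE), \code{absorbed_fraction}, \code{n}.
#' @export
simulateLatticeFlux <- function(D, konLattice, koffLattice, concentration,
                                siteDensity = 1625, L = NULL, dt = 1e-3,
                                nEvents = 20000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x0 <- sqrt(D / koffLattice)
  if (is.null(L)) L <- 12 * x0
  x <- runif(nEvents, 0, L)
  ## exponential unbinding clock per walker
  tDie <- rexp(nEvents, rate = koffLattice)
  alive <- rep(TRUE, nEvents)
  absorbed <- rep(FALSE, nEvents)
  t <- 0
  stepSD <- sqrt(2 * D * dt)
  while (any(alive)) {
    idx <- which(alive)
    xOld <- x[idx]
    xNew <- xOld + rnorm(length(idx), 0, stepSD)
    t <- t + dt
    ## endpoint crossing, plus the Brownian-bridge probability of an
    ## unobserved within-step excursion below 0 (removes the first-passage
    ## discretization bias)
    crossed <- xNew <= 0
    pos <- !crossed
    bridge <- exp(-xOld[pos] * xNew[pos] / (D * dt))
    crossed[pos] <- runif(sum(pos)) < bridge
    x[idx] <- xNew
    hit <- idx[crossed]
    absorbed[hit] <- TRUE
    alive[hit] <- FALSE
    dead <- idx[!crossed & tDie[idx] <= t]
    alive[dead] <- FALSE
    ## reflecting far boundary (far from the end, negligible influence)
    far <- idx[x[idx] > L]
    x[far] <- 2 * L - x[far]
  }
  frac <- mean(absorbed)
  bindRate <- konLattice * concentration * siteDensity * L   # events/s
  list(J0_per_s = bindRate * frac,
       se = bindRate * sqrt(frac * (1 - frac) / nEvents),
       absorbed_fraction = frac, n = nEvents)
}

#' Direct arrival rate at the end region
#'
#' N_p = kon_end * C * N_sites, the rate at which molecules bind the end
#' region directly from solution.
#'
#' @param konEnd s^-1 nM^-1 per dimer.
#' @param concentration nM.
#' @param nEndSites dimer sites in the end region.
#' @return arrival rate, s^-1.
#' @examples
#' directArrivalRate(22.6e-6, 10, 260)   # ~0.059
#' @export
directArrivalRate <- function(konEnd, concentration, nEndSites) {
  if (any(c(konEnd, concentration, nEndSites) <= 0))
    stop("all parameters must be > 0")
  konEnd * concentration * nEndSites
}

#' Percent of end arrivals delivered by 1D lattice diffusion
#'
#' 100 * J0 / Np: the diffusive flux as a percentage of the observed direct
#' arrival rate.
#'
#' @param J0 diffusive flux, s^-1.
#' @param Np direct arrival rate, s^-1 (> 0).
#' @return percent.
#' @examples
#' diffusionContribution(0.004, 0.067)   # ~6
#' @export
diffusionContribution <- function(J0, Np) {
  if (Np <= 0) stop("Np must be > 0")
  100 * J0 / Np
}
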