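## Single-molecule gating, event filtering/classification, per-dimer
## on-rates, dwell-time off-rate fits, and per-site / multivalent
## dissociation constants.

#' Build the single-molecule intensity gate
#'
#' A Gaussian is fitted to the probability distribution of event mean
#' intensities; events within mu +/- 2 sigma (closed interval) are accepted
#' as single molecules.  If a second histogram mode exceeds a quarter of the
#' dominant one (e.g. a monomer population next to the dimer peak), a
#' warning is raised and the gate centres on the dominant mode.
#'
#' @param intensities event mean intensities, A.U. (>= 50 events).
#' @param binWidth histogram bin width, A.U. (default: Freedman-Diaconis).
#' @return list with \code{mu}, \code{sigma}, \code{lower}, \code{upper}.
#' @examples
#' g <- list(mu = 300, sigma = 72.5, lower = 155, upper = 445)
#' @export
buildIntensityGate <- function(intensities, binWidth = NULL) {
  n <- length(intensities)
  if (n < 50L) stop("need >= 50 events to build an intensity gate")
  if (is.null(binWidth)) {
    binWidth <- 2 * stats::IQR(intensities) / n^(1 / 3)
    if (binWidth <= 0) binWidth <- diff(range(intensities)) / 30
  }
  edges <- seq(floor(min(intensities) / binWidth) * binWidth,
               ceiling(max(intensities) / binWidth) * binWidth + binWidth,
               by = binWidth)
  h <- graphics::hist(intensities, breaks = edges, plot = FALSE)
  pb <- h$counts / n
  xb <- h$mids
  ## crude mode scan for bimodality (separated by >= 3 bins)
  nb <- length(pb)
  valley <- NULL
  if (nb >= 5L) {
    loc <- which(pb[2:(nb - 1)] > pb[1:(nb - 2)] &
                 pb[2:(nb - 1)] >= pb[3:nb]) + 1L
    if (length(loc) >= 2L) {
      ord <- loc[order(pb[loc], decreasing = TRUE)]
      if (abs(ord[2] - ord[1]) >= 3L && pb[ord[2]] > 0.25 * pb[ord[1]]) {
        warning("bimodal intensity histogram; gating on the dominant mode")
        between <- seq(min(ord[1:2]), max(ord[1:2]))
        valley <- between[which.min(pb[between])]
      }
    }
  }
  ## fit only the contiguous region around the dominant mode so that a
  ## secondary (e.g. monomer) population cannot drag the centre
  imax <- which.max(pb)
  keepL <- imax; while (keepL > 1L && pb[keepL - 1L] >= 0.05 * pb[imax])
    keepL <- keepL - 1L
  keepR <- imax; while (keepR < nb && pb[keepR + 1L] >= 0.05 * pb[imax])
    keepR <- keepR + 1L
  if (!is.null(valley)) {
    if (valley < imax) keepL <- max(keepL, valley + 1L)
    else keepR <- min(keepR, valley - 1L)
  }
  sel <- keepL:keepR
  xbf <- xb[sel]; pbf <- pb[sel]
  fit <- minpack.lm::nlsLM(
    pbf ~ a * exp(-(xbf - mu)^2 / (2 * sigma^2)),
    start = list(a = max(pbf), mu = xb[imax], sigma = sd(intensities) / 2),
    lower = c(0, min(xb), binWidth / 10),
    upper = c(1, max(xb), diff(range(xb))))
  p <- coef(fit)
  mu <- unname(p["mu"]); sigma <- unname(p["sigma"])
  list(mu = mu, sigma = sigma, lower = mu - 2 * sigma,
       upper = mu + 2 * sigma)
}

#' Does an intensity fall inside the gate?
#'
#' Boundaries are inclusive (closed interval).
#'
#' @param intensity intensities, A.U. (vectorised).
#' @param gate list from \code{\link{buildIntensityGate}} (or any list with
#'   \code{lower} and \code{upper}).
#' @return logical vector.
#' @export
inGate <- function(intensity, gate) {
  intensity >= gate$lower & intensity <= gate$upper
}

#' Filter candidate events by intensity gate and dwell floor
#'
#' Retained events have an in-gate mean intensity AND a dwell strictly
#' exceeding the detection floor (2 kymograph pixels, ~200 ms at
#' 100 ms/frame).  Rejection reasons are tallied.
#'
#' @param events data.frame with \code{intensity} (or
#'   \code{mean_intensity}) and \code{dwell_s} columns.
#' @param gate intensity gate.
#' @param minDwell dwell floor, s.
#' @return the retained events, with attribute \code{rejections}: named
#'   counts (\code{intensity}, \code{dwell}, \code{both}).
#' @export
filterEvents <- function(events, gate, minDwell = 0.2) {
  intens <- if ("intensity" %in% names(events)) events$intensity
            else events$mean_intensity
  okI <- inGate(intens, gate)
  okD <- events$dwell_s > minDwell
  keep <- okI & okD
  out <- events[keep, , drop = FALSE]
  attr(out, "rejections") <- c(intensity = sum(!okI & okD),
                               dwell = sum(okI & !okD),
                               both = sum(!okI & !okD))
  out
}

#' Classify an event position as end or lattice binding
#'
#' Events inside the binding-region bounds (inclusive) or distal of them
#' (beyond the tip) are end binding; events proximal of the lower bound are
#' lattice binding.
#'
#' @param position_nm tip-relative positions, nm, distal positive
#'   (vectorised).
#' @param bounds numeric length 2: the binding-region interval from the
#'   pooled position-distribution fit (\code{bounds_nm} of
#'   \code{\link{fitPositionDistribution}}).
#' @return character vector, \code{"end"} or \code{"lattice"}.
#' @export
classifyRegion <- function(position_nm, bounds) {
  if (length(bounds) != 2L || bounds[1] > bounds[2])
    stop("bounds must be an ordered interval")
  ifelse(position_nm >= bounds[1], "end", "lattice")
}

#' Number of tubulin-dimer binding sites in a lattice region
#'
#' round(length / dimerRepeat) rings times protofilaments per ring; the
#' default geometry (13 pf, 8 nm repeat) gives 1625 dimers per um and 260
#' sites in a 160 nm end region.
#'
#' @param length_nm region length, nm.
#' @param protofilaments protofilaments per ring.
#' @param dimerRepeat axial dimer repeat, nm.
#' @return site count (dimers).
#' @examples
#' siteCount(160)    # 260
#' @export
siteCount <- function(length_nm, protofilaments = 13L, dimerRepeat = 8) {
  if (any(length_nm <= 0)) stop("length must be > 0")
  round(length_nm / dimerRepeat) * protofilaments
}

#' Per-dimer apparent association rate
#'
#' The number of binding events in a region divided by the number of
#' tubulin dimers it contains, the observation time and the molecule
#' concentration.
#'
#' @param nEvents binding events observed (>= 0).
#' @param nSites tubulin dimers in the region.
#' @param duration observation time, s.
#' @param concentration molecule concentration, nM.
#' @return kon, s^-1 nM^-1 per dimer.
#' @examples
#' computeOnRate(3, 260, 100, 10) * 1e6    # 11.5e-6 -> 11.5
#' @export
computeOnRate <- function(nEvents, nSites, duration, concentration) {
  if (nEvents < 0) stop("nEvents must be >= 0")
  if (nSites <= 0 || duration <= 0 || concentration <= 0)
    stop("nSites, duration and concentration must be > 0")
  nEvents / (nSites * duration * concentration)
}

#' End/lattice on-rate ratio, mean of per-microtubule ratios
#'
#' R_E/L is computed per microtubule as kon_end / kon_lattice and summarised
#' as the population mean +/- SEM (mean-of-ratios).  Because the ratio
#' estimator is convex in the lattice rate, the mean of per-microtubule
#' ratios exceeds the ratio of the mean rates on finite counts (Jensen);
#' the ratio-of-means is returned alongside for comparison.  Microtubules
#' with zero lattice rate are excluded and counted.
#'
#' @param konEnd,konLattice per-microtubule rates, matched vectors.
#' @return list with \code{mean}, \code{sem}, \code{n},
#'   \code{ratio_of_means}, \code{n_excluded}.
#' @export
computeREL <- function(konEnd, konLattice) {
  if (length(konEnd) != length(konLattice))
    stop("per-microtubule rate vectors must be matched")
  ok <- konLattice > 0
  if (!any(ok)) stop("all microtubules have zero lattice rate")
  r <- konEnd[ok] / konLattice[ok]
  list(mean = mean(r), sem = sd(r) / sqrt(length(r)), n = length(r),
       ratio_of_means = mean(konEnd[ok]) / mean(konLattice[ok]),
       n_excluded = sum(!ok))
}

#' Dwell-time distribution fit: off-rate and mean dwell
#'
#' The retained dwells are binned into a probability distribution and a
#' single exponential \code{a * exp(-koff * t)} is least-squares fitted
#' over [minDwell, Inf) — the convention behind the reported apparent
#' dissociation rates.  The arithmetic mean dwell and the shifted-
#' exponential MLE \code{1 / (mean - minDwell)} (which corrects the
#' detection-floor truncation exactly, by memorylessness) are reported
#' alongside as cross-checks.
#'
#' @param dwells dwell times, s (>= 30).
#' @param minDwell detection floor, s.
#' @param binWidth histogram bin width, s.
#' @param residualWarn warn if the exponential fit's relative residual norm
#'   exceeds this (non-exponential shape).
#' @return list with \code{koff_fit} (s^-1, exponential fit),
#'   \code{mean_dwell} (s), \code{koff_mle} (s^-1, shifted-exponential
#'   MLE), \code{tau_mle} (s), \code{n}.
#' @export
fitDwellOffRate <- function(dwells, minDwell = 0, binWidth = 0.1,
                            residualWarn = 0.5) {
  dwells <- dwells[dwells >= minDwell]
  n <- length(dwells)
  if (n < 30L) stop("need >= 30 dwells")
  meanDwell <- mean(dwells)
  tauMLE <- meanDwell - minDwell
  edges <- seq(minDwell, max(dwells) + binWidth, by = binWidth)
  h <- graphics::hist(dwells, breaks = edges, plot = FALSE)
  pb <- h$counts / n
  xb <- h$mids
  fit <- minpack.lm::nlsLM(pb ~ a * exp(-k * xb),
                           start = list(a = max(pb), k = 1 / tauMLE),
                           lower = c(0, 1e-6))
  k <- unname(coef(fit)["k"])
  rel <- sqrt(sum(residuals(fit)^2)) / sqrt(sum(pb^2))
  if (rel > residualWarn)
    warning("dwell distribution deviates from a single exponential ",
            "(relative residual ", signif(rel, 2), ")")
  list(koff_fit = k, mean_dwell = meanDwell, koff_mle = 1 / tauMLE,
       tau_mle = tauMLE, n = n)
}

#' Per-dimer dissociation constant
#'
#' Kd = koff / kon, converted from nM to uM.
#'
#' @param koff dissociation rate, s^-1.
#' @param kon association rate, s^-1 nM^-1 per dimer.
#' @return Kd, uM per tubulin dimer.
#' @examples
#' computeKd(1.56, 22.6e-6)    # ~69 uM
#' @export
computeKd <- function(koff, kon) {
  if (any(kon <= 0)) stop("kon must be > 0")
  (koff / kon) / 1000      # nM -> uM
}

#' Effective multivalent dissociation constant of the end region
#'
#' Treating the end as a multivalent receptor with \code{nSites}
#' independent dimer sites, the concentration at which the first molecule
#' is expected bound is Kd_site / N (first-arrival approximation), dropping
#' the per-site affinity from the micromolar to the nanomolar range.
#'
#' @param KdSite per-dimer Kd, uM.
#' @param nSites dimer sites in the end region (>= 1).
#' @return effective Kd, nM.
#' @examples
#' effectiveKd(69, 260)    # ~265 nM
#' @export
effectiveKd <- function(KdSite, nSites) {
  if (any(nSites < 1)) stop("nSites must be >= 1")
  KdSite * 1000 / nSites
}

#' Effective Kd under the half-occupancy definition
#'
#' Alternative convention: the concentration at which P(>= 1 site bound) is
#' one half, Kd_site * ln(2) / N for N independent weak sites.  Provided
#' for comparison; \code{\link{effectiveKd}} is the default convention.
#'
#' @inheritParams effectiveKd
#' @return effective Kd, nM.
#' @export
effectiveKdHalfOccupancy <- function(KdSite, nSites) {
  if (any(nSites < 1)) stop("nSites must be >= 1")
  KdSite * 1000 * log(2) / nSites
}

#' Full kinetics summary for one condition
#'
#' Convenience wrapper assembling per-microtubule on-rates, R_E/L, dwell
#' fits and dissociation constants from a filtered, classified event table.
#'
#' @param events data.frame with \code{mt_id}, \code{region}
#'   (\code{"end"}/\code{"lattice"}) and \code{dwell_s}.
#' @param nEndSites,nLatticeSites dimer sites per region (lattice may be a
#'   per-microtubule named vector).
#' @param duration observation time, s.
#' @param concentration nM.
#' @param minDwell detection floor for the dwell fits, s.
#' @return list: per-microtubule data.frame, \code{R_EL}, dwell fits and
#'   Kds per region, event/microtubule counts.
#' @export
rateSummary <- function(events, nEndSites, nLatticeSites, duration,
                        concentration, minDwell = 0.2) {
  mts <- sort(unique(events$mt_id))
  perMT <- do.call(rbind, lapply(mts, function(m) {
    sub <- events[events$mt_id == m, ]
    nLat <- if (length(nLatticeSites) > 1L)
      nLatticeSites[[as.character(m)]] else nLatticeSites
    data.frame(
      mt_id = m,
      kon_end = computeOnRate(sum(sub$region == "end"), nEndSites,
                              duration, concentration),
      kon_lattice = computeOnRate(sum(sub$region == "lattice"), nLat,
                                  duration, concentration))
  }))
  rel <- computeREL(perMT$kon_end, perMT$kon_lattice)
  endDwell <- fitDwellOffRate(events$dwell_s[events$region == "end"],
                              minDwell = minDwell)
  latDwell <- fitDwellOffRate(events$dwell_s[events$region == "lattice"],
                              minDwell = minDwell)
  konE <- mean(perMT$kon_end); konL <- mean(perMT$kon_lattice)
  list(per_microtubule = perMT,
       kon_end = konE,
       kon_end_sem = sd(perMT$kon_end) / sqrt(nrow(perMT)),
       kon_lattice = konL,
       kon_lattice_sem = sd(perMT$kon_lattice) / sqrt(nrow(perMT)),
       R_EL = rel,
       dwell_end = endDwell, dwell_lattice = latDwell,
       Kd_end_uM = computeKd(endDwell$koff_fit, konE),
       Kd_lattice_uM = computeKd(latDwell$koff_fit, konL),
       Kd_effective_nM = effectiveKd(computeKd(endDwell$koff_fit, konE),
                                     nEndSites),
       n_microtubules = nrow(perMT), n_events = nrow(events))
}
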