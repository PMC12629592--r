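## Microtubule dynamic instability statistics: growth-segment extraction
## from end traces, gamma lifetime fits, and the probability-based
## catastrophe frequency (discrete hazard).

#' Extract growth events from a microtubule end trace
#'
#' Segments the end-position trace wherever the slope sign changes and the
#' new sign is sustained for at least \code{minRun} frames.  Each growth
#' (positive-slope) segment yields a growth rate (least-squares slope) and
#' a lifetime (segment duration); a segment ending at the movie end is
#' censored, one followed by sustained shrinkage ends in catastrophe.
#'
#' @param time_s frame times, s.
#' @param pos_nm end positions, nm (NA allowed after disappearance).
#' @param minRun frames a slope sign must persist to count as a switch.
#' @return data.frame: \code{start_s}, \code{end_s}, \code{lifetime_s},
#'   \code{growth_rate_um_min}, \code{outcome}
#'   (\code{"catastrophe"}/\code{"censored"}).
#' @export
extractGrowthEvents <- function(time_s, pos_nm, minRun = 3L) {
  ok <- is.finite(pos_nm)
  lost <- !all(ok)                     # end disappeared before movie end
  time_s <- time_s[ok]; pos_nm <- pos_nm[ok]
  n <- length(pos_nm)
  if (n < 3L) return(data.frame(start_s = numeric(), end_s = numeric(),
                                lifetime_s = numeric(),
                                growth_rate_um_min = numeric(),
                                outcome = character()))
  s <- sign(diff(pos_nm))
  s[s == 0] <- 1
  ## sustained-run segmentation: a switch needs >= minRun frames of the
  ## new sign
  seg_start <- 1L
  cur <- s[1]
  bounds <- integer()
  i <- 1L
  while (i <= length(s)) {
    if (s[i] != cur) {
      run <- 1L
      while (i + run <= length(s) && s[i + run] == s[i]) run <- run + 1L
      if (run >= minRun) {
        bounds <- c(bounds, i)
        cur <- s[i]
        i <- i + run
        next
      } else i <- i + run
    } else i <- i + 1L
  }
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  out <- list()
  for (k in seq_along(starts)) {
    a <- starts[k]; b <- ends[k]
    if (b - a + 1L < 3L) next
    sl <- coef(lm(pos_nm[a:b] ~ time_s[a:b]))[[2]]   # nm/s
    if (sl <= 0) next
    followedByShrink <- k < length(starts)
    outcome <- if (followedByShrink || (k == length(starts) && lost))
      "catastrophe" else "censored"
    out[[length(out) + 1L]] <- data.frame(
      start_s = time_s[a], end_s = time_s[b],
      lifetime_s = time_s[b] - time_s[a],
      growth_rate_um_min = sl * 60 / 1000,
      outcome = outcome)
  }
  if (!length(out)) return(data.frame(start_s = numeric(),
                                      end_s = numeric(),
                                      lifetime_s = numeric(),
                                      growth_rate_um_min = numeric(),
                                      outcome = character()))
  do.call(rbind, out)
}

#' Gamma fit of microtubule lifetimes
#'
#' Maximum-likelihood gamma shape and scale on the uncensored lifetimes
#' (censored observations are excluded from the density fit, matching a
#' plain distribution fit; their count is reported).
#'
#' @param lifetimes lifetimes, s.
#' @param censored logical vector (default: none censored).
#' @return list with \code{shape}, \code{scale_s}, \code{mean_s}
#'   (= shape * scale), \code{loglik}, \code{n}, \code{n_censored}.
#' @export
fitGamma <- function(lifetimes, censored = NULL) {
  if (is.null(censored)) censored <- rep(FALSE, length(lifetimes))
  x <- lifetimes[!censored]
  if (length(x) < 30L) stop("need >= 30 uncensored lifetimes")
  if (sd(x) == 0) stop("degenerate lifetimes (all equal)")
  ## fitdistr explores invalid parameter corners en route; silence the
  ## transient dgamma NaN warnings
  fit <- suppressWarnings(MASS::fitdistr(x, "gamma"))
  shape <- unname(fit$estimate["shape"])
  scale <- 1 / unname(fit$estimate["rate"])
  list(shape = shape, scale_s = scale, mean_s = shape * scale,
       loglik = fit$loglik, n = length(x), n_censored = sum(censored))
}

#' Probability-based catastrophe frequency (discrete hazard)
#'
#' For each lifetime bin, the frequency is the number of catastrophes
#' observed in that bin divided by the number of microtubules that reached
#' the bin start.  Censored microtubules count as at risk up to their
#' censoring time and never as catastrophes.
#'
#' @param lifetimes observed lifetimes, s.
#' @param censored logical vector (default: none).
#' @param binWidth bin width, s.
#' @return data.frame: \code{bin_start_s}, \code{bin_end_s},
#'   \code{at_risk}, \code{catastrophes}, \code{frequency}.
#' @export
hazardCurve <- function(lifetimes, censored = NULL, binWidth = 30) {
  if (!length(lifetimes)) stop("empty lifetime input")
  if (binWidth <= 0) stop("binWidth must be > 0")
  if (is.null(censored)) censored <- rep(FALSE, length(lifetimes))
  nb <- floor(max(lifetimes) / binWidth) + 1L
  starts <- (seq_len(nb) - 1L) * binWidth
  atRisk <- vapply(starts, function(s) sum(lifetimes >= s), 1L)
  cat <- vapply(starts, function(s)
    sum(!censored & lifetimes >= s & lifetimes < s + binWidth), 1L)
  data.frame(bin_start_s = starts, bin_end_s = starts + binWidth,
             at_risk = atRisk, catastrophes = cat,
             frequency = ifelse(atRisk > 0, cat / atRisk, NA_real_))
}

#' Survival curve reconstructed from a hazard curve
#'
#' S at each bin end is the running product of (1 - frequency); on fully
#' uncensored data this telescopes to the empirical survival exactly.
#'
#' @param hazard data.frame from \code{\link{hazardCurve}}.
#' @return data.frame: \code{t_s} (bin ends), \code{survival}.
#' @export
survivalFromHazard <- function(hazard) {
  data.frame(t_s = hazard$bin_end_s,
             survival = cumprod(1 - hazard$frequency))
}

#' Empirical survival at given times
#'
#' Fraction of lifetimes at least each time (uncensored data), matching the
#' at-risk convention of \code{\link{hazardCurve}}.
#'
#' @param lifetimes lifetimes, s.
#' @param times evaluation times, s.
#' @return numeric vector of survival fractions.
#' @export
empiricalSurvival <- function(lifetimes, times) {
  vapply(times, function(t) mean(lifetimes >= t), 1)
}
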