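test_that("the erfc edge model recovers a noiseless edge to <0.1 nm", {
  p <- makeEdgeProfile(xe = 0, sigma = 120, px = 160)
  f <- fitEndProfile(p$x, p$y)
  expect_lt(abs(f$edge_pos_nm), 0.1)
  expect_equal(f$sigma_nm, 120, tolerance = 1e-3)
  expect_false(f$flagged)
  # mirrored orientation (plus end toward decreasing x)
  pm <- list(x = p$x, y = rev(p$y))
  fm <- fitEndProfile(pm$x, pm$y, mirror = TRUE)
  expect_lt(abs(fm$edge_pos_nm), 0.1)
})

test_that("noisy edge fits are unbiased (<2 nm) and match a grid search", {
  set.seed(31)
  xs <- replicate(200, {
    p <- makeEdgeProfile(xe = 512.3, sigma = 120, A = 400, bg = 100,
                         span = c(-1600, 2400), noisy = TRUE)
    fitEndProfile(p$x, p$y)$edge_pos_nm
  })
  # flagged fits (rare, reported as NA) are excluded downstream by contract
  expect_lt(sum(!is.finite(xs)), 5)
  expect_lt(abs(mean(xs, na.rm = TRUE) - 512.3), 2)
  # agreement with an exhaustive 0.1 nm grid search on single profiles
  set.seed(32)
  for (i in 1:5) {
    p <- makeEdgeProfile(xe = 512.3, sigma = 120, A = 400, bg = 100,
                         span = c(-1600, 2400), noisy = TRUE)
    lm_fit <- fitEndProfile(p$x, p$y)$edge_pos_nm
    grid_fit <- gridSearchEdge(p$x, p$y)
    expect_lt(abs(lm_fit - grid_fit), 5)
  }
})

test_that("molecule peaks are localized and pathologies are flagged", {
  x <- seq(0, 3200, by = 160)
  y <- 50 + 400 * exp(-(x - 1000)^2 / (2 * 130^2))
  f <- fitMoleculePeak(x, y)
  expect_lt(abs(f$center_nm - 1000), 0.1)
  expect_false(f$flagged)
  # flat profile
  expect_true(fitMoleculePeak(x, rep(100, length(x)))$flagged)
  # two comparable maxima
  y2 <- y + 380 * exp(-(x - 2400)^2 / (2 * 130^2))
  f2 <- fitMoleculePeak(x, y2)
  expect_true(f2$flagged)
  expect_match(f2$flag_reason, "ambiguous")
})

test_that("event positions average peak-minus-edge over the dwell", {
  mkEnd <- function(e) list(edge_pos_nm = e, flagged = FALSE)
  mkPeak <- function(c) list(center_nm = c, flagged = FALSE)
  ev <- localizeEvent(list(mkEnd(0), mkEnd(0)),
                      list(mkPeak(-60), mkPeak(-70)))
  expect_equal(ev$mean_pos_nm, -65)
  expect_false(ev$rejected)
  # translation invariance: shifting both by a constant changes nothing
  ev2 <- localizeEvent(list(mkEnd(1000), mkEnd(1000)),
                       list(mkPeak(940), mkPeak(930)))
  expect_equal(ev2$mean_pos_nm, ev$mean_pos_nm)
  # a growing end under a lab-stationary molecule: relative position
  # recedes at the growth rate
  v <- 8 * 1000 / 60
  ends <- lapply(0:4, function(k) mkEnd(k * 0.1 * v))
  peaks <- lapply(0:4, function(k) mkPeak(100))
  ev3 <- localizeEvent(ends, peaks)
  expect_equal(diff(ev3$rel_pos_nm), rep(-0.1 * v, 4))
  # flagged frames are dropped; fewer than 2 valid frames rejects
  ev4 <- localizeEvent(list(mkEnd(0), list(edge_pos_nm = 0, flagged = TRUE)),
                       list(mkPeak(-60), mkPeak(-70)))
  expect_true(ev4$rejected)
})

test_that("Gaussian FWHM is exactly 2*sqrt(2 ln 2)*sigma and is recovered", {
  set.seed(33)
  pos <- rnorm(152, -10, 68.8)
  f <- fitPositionDistribution(pos, "gaussian", binWidth = 20)
  expect_identical(f$fwhm_nm, 2 * sqrt(2 * log(2)) * f$sigma)
  # 68.8 nm sigma corresponds to a 162 nm binding region
  expect_equal(f$fwhm_nm, 162, tolerance = 0.15)
  expect_equal(f$bounds_nm, f$mu + c(-1, 1) * f$fwhm_nm / 2)
  expect_error(fitPositionDistribution(pos[1:10], "gaussian"), ">= 30")
})

test_that("EMG FWHM agrees with a dense-grid oracle to <0.1 nm", {
  set.seed(34)
  pos <- rnorm(4000, 0, 50) - rexp(4000, 1 / 80)
  f <- fitPositionDistribution(pos, "emg", binWidth = 20, tail = "negative")
  # oracle: dense evaluation of the fitted density, half-maximum crossings
  # by bisection
  g <- seq(min(pos) - 200, max(pos) + 200, length.out = 200001L)
  d <- emgDensity(g, f$mu, f$sigma, f$lambda, tail = "negative")
  half <- max(d) / 2
  lo <- g[min(which(d >= half))]; hi <- g[max(which(d >= half))]
  oracle <- hi - lo
  expect_lt(abs(f$fwhm_nm - oracle), 0.1)
})

test_that("two-color distances recover the modal offset and sign", {
  ident <- lapply(1:40, function(i) list(a = c(5, 7), b = c(5, 7)))
  expect_equal(twoColorDistance(ident)$mean_nm, 0)
  set.seed(35)
  evs <- lapply(1:62, function(i) {
    nf <- sample(2:8, 1)
    tru <- rnorm(1, -65, 40)
    list(a = rnorm(nf, 0, 18), b = rnorm(nf, tru, 18))
  })
  tc <- twoColorDistance(evs, binWidth = 20)
  expect_lt(abs(tc$mode_nm - (-65)), 20)
  # fraction distal of the origin for an exact N(-65, 40) population:
  # Phi(-65/40) ~ 5%
  set.seed(36)
  d <- rnorm(4000, -65, 40)
  evs2 <- lapply(d, function(x) list(a = 0, b = x))
  frac <- twoColorDistance(evs2)$fraction_positive
  p <- pnorm(-65 / 40)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 4000))
})

test_that("precision deconvolution inverts quadrature convolution exactly", {
  expect_equal(as.numeric(deconvolvePrecision(120, 120)), 0)
  sigI <- sqrt(18^2 + 120^2)   # 121.34
  expect_equal(as.numeric(deconvolvePrecision(sigI, 120)), 18)
  # exact inverse across a sweep
  sigO <- seq(0.5, 60, by = 0.5)
  back <- deconvolvePrecision(sqrt(sigO^2 + 120^2), 120)
  expect_equal(as.numeric(back), sigO)
  # noise-dominated records are excluded and counted
  out <- deconvolvePrecision(c(119, 125), 120)
  expect_true(is.na(out[1]))
  expect_equal(attr(out, "n_excluded"), 1L)
})

test_that("per-bead width scatter shrinks with photon count", {
  cfgLo <- simulationConfig(nFrames = 2L, imageShape = c(160L, 160L),
                            psfSigma = c(beads = 120), seed = 41L,
                            background = 50)
  bsLo <- renderBeadStack(cfgLo, nBeads = 25L, brightness = 1500,
                          noise = TRUE)
  bsHi <- renderBeadStack(cfgLo, nBeads = 25L, brightness = 60000,
                          noise = TRUE)
  sLo <- attr(suppressWarnings(estimatePsfSigma(bsLo)), "per_bead")$beads
  sHi <- attr(suppressWarnings(estimatePsfSigma(bsHi)), "per_bead")$beads
  expect_gt(sd(sLo), 2 * sd(sHi))
})
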