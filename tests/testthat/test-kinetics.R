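test_that("the intensity gate is mu +/- 2 sigma with closed boundaries", {
  # the dimer population: 300 +/- 72.5 A.U. gives the gate [155, 445]
  gate <- list(mu = 300, sigma = 72.5, lower = 155, upper = 445)
  expect_true(inGate(155, gate))
  expect_true(inGate(445, gate))
  expect_false(inGate(154.99, gate))
  set.seed(51)
  g <- buildIntensityGate(rnorm(800, 300, 72.5))
  expect_equal(g$mu, 300, tolerance = 0.02)
  expect_equal(g$upper - g$lower, 4 * 72.5, tolerance = 0.1)
  # monomer contamination: gate still centres on the dominant dimer mode
  set.seed(52)
  mix <- c(rnorm(700, 300, 60), rnorm(250, 130, 25))
  gm <- suppressWarnings(buildIntensityGate(mix))
  expect_lt(abs(gm$mu - 300), 30)
  expect_warning(buildIntensityGate(mix), "bimodal")
})

test_that("gate acceptance of a pure Gaussian population is ~95.45%", {
  set.seed(53)
  i <- rnorm(2e5, 300, 72.5)
  gate <- list(lower = 300 - 2 * 72.5, upper = 300 + 2 * 72.5)
  acc <- mean(inGate(i, gate))
  p <- pnorm(2) - pnorm(-2)     # erf(2/sqrt(2)) = 0.9545
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / 2e5))
})

test_that("event filtering applies gate and dwell floor and tallies reasons", {
  gate <- list(lower = 155, upper = 445)
  ev <- data.frame(intensity = c(300, 300, 500, 500, 445),
                   dwell_s = c(0.15, 0.25, 0.25, 0.1, 0.3))
  out <- filterEvents(ev, gate, minDwell = 0.2)
  expect_equal(nrow(out), 2L)            # rows 2 and 5
  rej <- attr(out, "rejections")
  expect_equal(sum(rej), 3L)
  expect_equal(unname(rej["dwell"]), 1L)
  expect_equal(unname(rej["intensity"]), 1L)
  expect_equal(unname(rej["both"]), 1L)
})

test_that("region classification is inclusive at bounds and order-preserving", {
  bounds <- c(-81, 81)
  expect_equal(classifyRegion(-81, bounds), "end")
  expect_equal(classifyRegion(-500, bounds), "lattice")
  expect_equal(classifyRegion(200, bounds), "end")   # beyond-tip counts end
  pos <- seq(-400, 400, by = 40)
  cls <- classifyRegion(pos, bounds)
  expect_true(all(diff(as.integer(factor(cls, c("lattice", "end")))) >= 0))
})

test_that("site counting follows the 13-pf, 8-nm dimer geometry", {
  expect_equal(siteCount(160), 260)
  expect_equal(siteCount(10000), 16250)
  expect_equal(siteCount(8), 13)
})

test_that("the on-rate estimator is events per dimer per second per nM", {
  expect_equal(computeOnRate(3, 260, 100, 10), 11.5e-6, tolerance = 5e-3)
  expect_equal(computeOnRate(0, 260, 100, 10), 0)
  expect_error(computeOnRate(3, 0, 100, 10), "> 0")
  # unbiased under Poisson arrivals: 66 microtubules at the end on-rate
  cfg <- simulationConfig(nFrames = 1000L, seed = 54L)
  mts <- do.call(rbind, lapply(1:66, function(i)
    makeMT(id = i, lifetime = 1e6, lattice = 4000)))
  b <- simulateBinding(cfg, mts, konEnd = 22.6e-6, konLattice = 0,
                       concentration = 10, seed = 55)
  nEnd <- sum(b$events$site_class == "end")
  kon <- computeOnRate(nEnd, 260 * 66, 100, 10)
  se <- sqrt(22.6e-6 * 10 * 260 * 100 * 66) / (260 * 66 * 100 * 10)
  expect_lt(abs(kon - 22.6e-6), 2 * se)
})

test_that("R_E/L is the mean of per-microtubule ratios with SEM", {
  r <- computeREL(c(10, 13, 16), c(1, 1, 1))
  expect_equal(r$mean, 13)
  expect_equal(r$sem, sd(c(10, 13, 16)) / sqrt(3), tolerance = 1e-9)
  expect_equal(r$sem, 1.732, tolerance = 1e-3)
  # Jensen: with high per-microtubule counts, mean-of-ratios converges to
  # the true homogeneous ratio
  set.seed(56)
  nE <- rpois(80, 2000); nL <- rpois(80, 250)
  r2 <- computeREL(nE / 260, nL / 260 * 8 / 8)
  expect_equal(r2$mean, 8, tolerance = 0.03)
  # zero-lattice microtubules are excluded with a count
  r3 <- computeREL(c(5, 6), c(1, 0))
  expect_equal(r3$n_excluded, 1L)
  expect_error(computeREL(c(1), c(0)), "zero lattice")
})

test_that("dwell fits report the mean, fit koff, and shifted MLE", {
  # the ATP plus-end condition: 966 events, 0.75 s mean dwell
  d <- simulateDwellSamples(0.75, 966, seed = 57)
  f <- fitDwellOffRate(d)
  expect_lt(abs(f$mean_dwell - 0.75), 2 * 0.75 / sqrt(966))
  expect_equal(f$koff_mle, 1 / f$mean_dwell)
  # truncated generation: the shifted MLE undoes the floor exactly in
  # expectation while the naive mean is inflated to floor + tau
  d2 <- simulateDwellSamples(0.55, 20000, minDwell = 0.2, seed = 58)
  f2 <- fitDwellOffRate(d2, minDwell = 0.2)
  expect_equal(f2$tau_mle, 0.55, tolerance = 0.02)
  expect_equal(f2$mean_dwell, 0.75, tolerance = 0.02)
  # the binned exponential fit recovers the generating rate
  expect_equal(f2$koff_fit, 1 / 0.55, tolerance = 0.1)
})

test_that("shifted-exponential MLE recovers tau across the working range", {
  for (tau in c(0.3, 1, 3)) {
    d <- simulateDwellSamples(tau, 5000, minDwell = 0.2,
                              seed = 59 + round(10 * tau))
    f <- fitDwellOffRate(d, minDwell = 0.2)
    expect_equal(f$tau_mle, tau, tolerance = 3 / sqrt(5000) * 2)
  }
})

test_that("dissociation constants follow Kd = koff/kon with unit care", {
  expect_equal(computeKd(1.56, 22.6e-6), 69, tolerance = 0.001)
  expect_equal(computeKd(2.96, 2.8e-6), 1057, tolerance = 0.001)
  expect_equal(computeKd(2 * 1.56, 22.6e-6), 2 * computeKd(1.56, 22.6e-6))
  expect_error(computeKd(1, 0), "kon")
})

test_that("the multivalent end drops the effective Kd to nanomolar", {
  expect_equal(effectiveKd(69, 260), 265.4, tolerance = 1e-3)
  expect_equal(effectiveKd(69, 1), 69000)
  expect_equal(effectiveKdHalfOccupancy(69, 260),
               effectiveKd(69, 260) * log(2))
  # brute-force independent-sites oracle: concentration where the expected
  # bound count is 1 equals Kd/(N-1), within 1% of Kd/N for N >= 100
  Kd <- 69; N <- 260
  f <- function(C) N * C / (C + Kd * 1000) - 1   # C in nM
  Cstar <- uniroot(f, c(1, 1e6))$root
  expect_equal(Cstar, effectiveKd(Kd, N), tolerance = 0.01)
})

test_that("rateSummary assembles a coherent per-condition picture", {
  set.seed(60)
  nMT <- 40; Tobs <- 200; C <- 10
  ev <- do.call(rbind, lapply(seq_len(nMT), function(m) {
    ne <- rpois(1, 22.6e-6 * C * 260 * Tobs)
    nl <- rpois(1, 2.8e-6 * C * 6500 * Tobs)
    if (ne + nl == 0) return(NULL)
    data.frame(mt_id = m,
               region = c(rep("end", ne), rep("lattice", nl)),
               dwell_s = 0.2 + c(rexp(ne, 1 / 0.55), rexp(nl, 1 / 0.42)))
  }))
  rs <- rateSummary(ev, nEndSites = 260, nLatticeSites = 6500,
                    duration = Tobs, concentration = C)
  expect_equal(rs$kon_end, 22.6e-6, tolerance = 0.15)
  expect_equal(rs$kon_lattice, 2.8e-6, tolerance = 0.15)
  expect_gt(rs$R_EL$mean, 4)
  expect_equal(rs$Kd_effective_nM,
               effectiveKd(rs$Kd_end_uM, 260))
  # identity: Kd * kon = koff after unit conversion
  expect_equal(rs$Kd_end_uM * 1000 * rs$kon_end, rs$dwell_end$koff_fit)
})
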