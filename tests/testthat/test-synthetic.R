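cfg100 <- simulationConfig(nFrames = 1000L, imageShape = c(48L, 192L),
                           seed = 11L)

test_that("gamma lifetimes have the configured distribution and censoring", {
  # shape 1 reduces to exponential with the scale as the mean
  mts <- simulateDynamics(cfg100, lifetimeShape = 1, lifetimeScale = 30,
                          nMicrotubules = 4000L, seed = 1)
  expect_equal(mean(mts$lifetime_s), 30, tolerance = 3 / sqrt(4000) * 1)
  # mean lifetime at the control condition: shape * scale = 323.4 s
  mts2 <- simulateDynamics(cfg100, lifetimeShape = 3, lifetimeScale = 107.8,
                           nMicrotubules = 443L, seed = 2)
  sem <- sqrt(3) * 107.8 / sqrt(443)
  expect_lt(abs(mean(mts2$lifetime_s) - 323.4), 3 * sem)
  # censoring at the movie end is flagged, never dropped
  expect_equal(nrow(mts2), 443L)
  expect_true(all(mts2$censored == (mts2$lifetime_s > 100)))
  expect_true(all(mts2$observed_lifetime_s <= 100))
  expect_error(simulateDynamics(cfg100, lifetimeShape = -1), "> 0")
})

test_that("linear growth displaces the end at the configured speed", {
  mt <- makeMT(anchor_x = 1000, rate = 0.8, lifetime = 120)
  expect_equal(endPositionAt(mt, 60), 1000 + 800)
  expect_true(is.na(endPositionAt(mt, 150)))
})

test_that("binding arrivals are Poisson with rate kon*C*Nsites", {
  # 260-site end window, kon 22.6e-6 /s/nM/dimer, 10 nM, 100 s observation:
  # expected arrivals 5.876 per microtubule
  cfg <- simulationConfig(nFrames = 1000L, seed = 3L)
  mts <- do.call(rbind, lapply(1:120, function(i)
    makeMT(id = i, lifetime = 1e6, lattice = 4000)))
  b <- simulateBinding(cfg, mts, konEnd = 22.6e-6, konLattice = 0,
                       concentration = 10, seed = 4)
  nEnd <- sum(b$events$site_class == "end")
  mu <- 22.6e-6 * 10 * 260 * 100 * 120
  expect_lt(abs(nEnd - mu), 3 * sqrt(mu))
  # zero on-rates give zero events
  b0 <- simulateBinding(cfg, mts[1:5, ], konEnd = 0, konLattice = 0,
                        seed = 5)
  expect_equal(nrow(b0$events), 0L)
})

test_that("lattice-bound molecules take Brownian steps of variance 2 D dt", {
  cfg <- simulationConfig(nFrames = 600L, seed = 6L)
  mts <- makeMT(lifetime = 1e6, lattice = 60000)
  b <- simulateBinding(cfg, mts, konEnd = 0, konLattice = 50e-6,
                       tauLattice = 2, D = 0.023, concentration = 10,
                       seed = 7)
  steps <- unlist(lapply(b$traces, function(tr) diff(tr$rel_pos_nm)))
  expect_gt(length(steps), 1500)
  # sd of per-frame steps: sqrt(2 * 0.023 * 0.1) um = 67.8 nm
  sdTheory <- sqrt(2 * 0.023 * 0.1) * 1000
  expect_lt(abs(sd(steps) - sdTheory),
            3 * sdTheory / sqrt(2 * length(steps)))
})

test_that("dwell samples honour the detection-floor truncation", {
  expect_equal(mean(simulateDwellSamples(1, 2e5, seed = 8)), 1,
               tolerance = 0.01)
  # memorylessness: conditioning on exceeding 0.2 s shifts the mean to
  # 0.2 + tau
  d <- simulateDwellSamples(0.55, 2e5, minDwell = 0.2, seed = 9)
  expect_equal(mean(d), 0.75, tolerance = 0.01)
  expect_true(all(d > 0.2))
  expect_length(simulateDwellSamples(1, 0), 0)
  expect_error(simulateDwellSamples(0, 10), "tau")
})

test_that("trajectory increments are Brownian and the track floor holds", {
  tr0 <- simulateTrajectories(0, 5, nFrames = 10, seed = 10)
  expect_true(all(tr0$pos_um == 0))
  tr <- simulateTrajectories(0.023, 100, nFrames = 101, dt = 0.1, seed = 11)
  inc <- unlist(lapply(split(tr, tr$track), function(t) diff(t$pos_um)))
  Dhat <- var(inc) / (2 * 0.1)
  se <- 0.023 * sqrt(2 / length(inc)) / (2 * 0.1) * 2 * 0.1
  expect_lt(abs(Dhat - 0.023), 3 * se)
  expect_error(simulateTrajectories(0.023, 5, nFrames = 3), ">= 4")
})

test_that("rendering conserves photons and is seed-deterministic", {
  cfg <- simulationConfig(nFrames = 3L, imageShape = c(48L, 192L),
                          seed = 12L)
  mts <- makeMT(anchor_x = 15000, lattice = 8000, lifetime = 1e6)
  mv <- renderMovie(cfg, mts, noise = FALSE)
  fr <- getChannel(mv, "microtubule")[, , 1]
  # noiseless frame sum = background * n_pixels + line brightness * length
  expect_equal(sum(fr), 100 * 48 * 192 + 2000 * 8, tolerance = 1e-8)
  mvA <- renderMovie(cfg, mts, noise = TRUE)
  mvB <- renderMovie(cfg, mts, noise = TRUE)
  expect_identical(getChannel(mvA, "microtubule"),
                   getChannel(mvB, "microtubule"))
})

test_that("a noiseless rendered emitter sits at its true sub-pixel centre", {
  cfg <- simulationConfig(nFrames = 1L, imageShape = c(32L, 64L), seed = 1L)
  mts <- makeMT(anchor_x = 200, anchor_y = 16 * 160, lattice = 100,
                lifetime = 1e-9)  # microtubule gone instantly
  b <- list(events = data.frame(molecule_id = 1L, mt_id = 1L,
                                site_class = "end", arrival_time_s = 0,
                                dwell_s = 1, intensity = 500,
                                channel = "molecule"),
            traces = list(data.frame(time_s = 0, rel_pos_nm = 4937.3)))
  mv <- renderMovie(cfg, mts, b, noise = FALSE)
  fr <- getChannel(mv, "molecule")[, , 1] - 100
  xs <- (seq_len(64) - 0.5) * 160
  cx <- sum(colSums(fr) * xs) / sum(fr)
  expect_equal(cx, 200 + 4937.3, tolerance = 0.1)
})

test_that("bead stacks record truth and support PSF recovery", {
  cfg <- simulationConfig(nFrames = 4L, imageShape = c(128L, 128L),
                          psfSigma = c(green = 120, red = 150), seed = 13L)
  bs <- renderBeadStack(cfg, nBeads = 18L, noise = FALSE)
  expect_setequal(channelNames(bs), c("green", "red"))
  expect_length(bs@metadata$bead_x_nm, 18L)
  est <- suppressWarnings(estimatePsfSigma(bs))
  expect_equal(unname(est["green"]), 120, tolerance = 0.02)
  expect_equal(unname(est["red"]), 150, tolerance = 0.02)
})
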