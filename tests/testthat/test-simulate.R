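# Monte-Carlo TCSPC simulator: inverse-transform sampling, wrap-around,
# after-pulsing background, stack assembly.

test_that("emission times follow the exponential law", {
  expect_identical(sampleEmissionTimes(0, 2.5), numeric(0))
  t <- sampleEmissionTimes(1e6, 2.5, seed = 11)
  se <- 2.5 / sqrt(1e6)
  expect_lt(abs(mean(t) - 2.5), 3 * se)
  # goodness of fit against the closed-form CDF
  t2 <- sampleEmissionTimes(1e5, 1.0, seed = 12)
  ks <- suppressWarnings(ks.test(t2, pexp, rate = 1))
  expect_gt(ks$p.value, 0.01)
  expect_error(sampleEmissionTimes(10, -1), "tau")
})

test_that("excitation times follow the Gaussian IRF", {
  expect_equal(sampleExcitationTimes(5, 3.2, 0), rep(3.2, 5))
  t <- sampleExcitationTimes(1e6, 3.2, 0.15, seed = 13)
  expect_lt(abs(mean(t) - 3.2), 3 * 0.15 / sqrt(1e6))
  expect_lt(abs(sd(t) - 0.15), 3 * 0.15 / sqrt(2 * 1e6))
  z <- (t - mean(t)) / sd(t)
  expect_lt(abs(mean(z^3)), 3 * sqrt(6 / 1e6))  # skewness ~ N(0, 6/n)
  expect_error(sampleExcitationTimes(10, 3.2, -0.1), "sigma")
})

test_that("simulated decays conserve photons and add the right background", {
  # period == acquisition window, so wrap-around loses nothing
  cfg <- defaultCfg(ap = 0.05, repRate = 40)
  h <- simulateDecay(cfg, 2.5, 5000, seed = 1)
  expect_equal(totalCounts(h), 5000 + round(0.05 * 5000))
  h0 <- simulateDecay(cfg, 2.5, 0, seed = 1)
  expect_equal(totalCounts(h0), 0)
  # with seed fixed, two runs are bit-identical
  expect_identical(counts(simulateDecay(cfg, 2.5, 5000, seed = 7)),
                   counts(simulateDecay(cfg, 2.5, 5000, seed = 7)))
})

test_that("histogram centre-of-mass matches the lifetime when T >> tau", {
  cfg <- simConfig(afterpulsing = 0, irfCentre = 0, irfSigma = 0,
                   acqWindow = 25, nBins = 256)
  h <- simulateDecay(cfg, 1.0, 2e5, seed = 21)
  cm <- centreOfMass(h)
  expect_lt(abs(cm - 1.0), 3 * 1.0 / sqrt(2e5) + binWidth(cfg))
})

test_that("incomplete decays wrap into the early bins", {
  # tau = 5 ns at 80 MHz: period 12.5 ns, tail wraps in front of the IRF
  cfg <- simConfig(afterpulsing = 0, repRate = 80, acqWindow = 25)
  h <- simulateDecay(cfg, 5, 5e4, seed = 31)
  dt <- binWidth(cfg)
  preIRF <- sum(counts(h)[seq_len(floor(2.5 / dt))])  # well before t0 = 3.2
  expect_gt(preIRF, 0)
  # everything lives below the 12.5 ns period
  expect_equal(sum(counts(h)[(floor(12.5 / dt) + 2):256]), 0)
})

test_that("background photons are uniform over the acquisition window", {
  # make background dominate: tiny tau confines the signal to early bins
  cfg <- simConfig(afterpulsing = 5, irfCentre = 0.1, irfSigma = 0,
                   acqWindow = 25, nBins = 256)
  h <- simulateDecay(cfg, 0.01, 2000, seed = 41)
  tailBins <- counts(h)[31:256]  # signal-free region
  chi <- chisq.test(tailBins)
  expect_gt(chi$p.value, 0.01)
})

test_that("stacks are reproducible and consistent with single decays", {
  cfg <- simConfig(lifetimeMap = matrix(2.5, 1, 1),
                   photonMap = matrix(1000, 1, 1),
                   afterpulsing = 0.05, seed = 5L)
  stk <- simulateStack(cfg)
  h <- simulateDecay(cfg, 2.5, 1000, seed = f3flim:::.pixelSeed(5L, 1, 1))
  expect_identical(as.integer(cube(stk)[, 1, 1]), as.integer(counts(h)))
  expect_identical(cube(simulateStack(cfg)), cube(stk))
  expect_equal(stk@lifetimeMap, matrix(2.5, 1, 1))
})

test_that("photon-count gradients are realised per column", {
  nGrad <- round(seq(100, 5000, length.out = 8))
  cfg <- simConfig(lifetimeMap = matrix(2.5, 4, 8),
                   photonMap = matrix(rep(nGrad, each = 4), 4, 8),
                   afterpulsing = 0, seed = 9L)
  stk <- simulateStack(cfg)
  colTotals <- apply(cube(stk), 3, sum) / 4
  expect_true(all(diff(colTotals) > 0))
  expect_true(all(abs(colTotals - nGrad) / nGrad < 0.05))
})

test_that("simulator rejects inconsistent configurations", {
  expect_error(simConfig(lifetimeMap = matrix(2.5, 2, 2),
                         photonMap = matrix(100, 3, 2)), "shape")
  expect_error(simConfig(lifetimeMap = -1), "positive")
  expect_error(simConfig(repRate = 1e6), "period")
})
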