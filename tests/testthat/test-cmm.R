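# Centre-of-mass estimation chain: background subtraction, discrete first
# moment, IRF moment, finite-window correction, pixel and stack sweeps.

test_that("pre-rise background subtraction removes a uniform offset", {
  flat <- DecayHistogram(rep(7, 64), binWidth = 0.1)
  r <- subtractBackground(flat, nPreBins = 10)
  expect_equal(r$level, 7)
  expect_equal(r$counts, rep(0, 64))

  decay <- noiselessDecay(2, dt = 0.1, nBins = 64) * 1000
  r0 <- subtractBackground(c(0, 0, 0, 0, decay[1:60]), nPreBins = 4)
  expect_equal(r0$level, 0)
  expect_equal(r0$counts, c(0, 0, 0, 0, decay[1:60]))

  # exact offset k comes straight back out of the pre-rise bins
  shifted <- c(0, 0, 0, 0, decay[1:60]) + 3.5
  rk <- subtractBackground(shifted, nPreBins = 4)
  expect_equal(rk$level, 3.5)
  expect_equal(rk$counts, c(0, 0, 0, 0, decay[1:60]))
  expect_error(subtractBackground(flat, nPreBins = 64), "nPreBins")
})

test_that("discrete centre-of-mass matches hand-computable cases", {
  expect_equal(centreOfMass(c(1, 0, 0, 0), binWidth = 0.1), 0.05)
  # uniform decay over n bins: window midpoint
  expect_equal(centreOfMass(rep(3, 50), binWidth = 0.1), 2.5)
  # all-zero or net-negative windows flag, not error
  expect_true(is.na(centreOfMass(rep(0, 10), binWidth = 0.1)))
  expect_true(is.na(centreOfMass(rep(-1, 10), binWidth = 0.1)))
})

test_that("binned centre-of-mass agrees with the closed form", {
  dt <- 25 / 256
  cm <- centreOfMass(noiselessDecay(2, dt, 256), binWidth = dt)
  expect_lt(abs(cm - closedFormCM(2, 25)) / closedFormCM(2, 25), 1e-3)

  # property: second-order binning error across random lifetimes/windows
  set.seed(42)
  for (i in 1:100) {
    tau <- runif(1, 0.5, 8)
    nb <- sample(c(128, 256, 512), 1)
    Tw <- runif(1, 10, 30)
    d <- Tw / nb
    cmB <- centreOfMass(noiselessDecay(tau, d, nb), binWidth = d)
    expect_lt(abs(cmB - closedFormCM(tau, Tw)), d^2 / (4 * tau))
  }
})

test_that("IRF moments follow the discrete centre-of-mass convention", {
  dt <- 25 / 256
  # delta IRF in bin k (0-based): moment at the bin midpoint
  delta <- rep(0, 256); delta[33] <- 500   # bin k = 32
  expect_equal(irfMoment(DecayHistogram(delta, dt)), 32 * dt + dt / 2)
  # symmetric two-bin IRF: midpoint between the two bin centres
  two <- rep(0, 256); two[33] <- 200; two[34] <- 200
  expect_equal(irfMoment(DecayHistogram(two, dt)), (32.5 + 0.5) * dt)
  # Gaussian model: moment equals the centre up to binning error
  expect_lt(abs(irfMoment(defaultIRF(), binWidth = dt, nBins = 256) - 3.2),
            dt / 10)
  # sampled Gaussian IRF agrees with its analytic moment
  cfg <- defaultCfg()
  hIRF <- simulateIRF(cfg, 1e6, seed = 3)
  expect_lt(abs(irfMoment(hIRF) - 3.2), 3 * 0.15 / sqrt(1e6) + dt / 10)
})

test_that("finite-window correction inverts the truncation relation", {
  # negligible correction deep in the T >> tau regime
  expect_lt(abs(finiteWindowCorrect(1, window = 25) - 1), 1e-6)
  # worked value: CM of tau = 2 over Ta = 6.25 maps back to 2
  expect_equal(finiteWindowCorrect(closedFormCM(2, 6.25), window = 6.25),
               2, tolerance = 1e-3)
  # round-trip property over tau/Ta in [0.04, 0.8], tolerance mode
  set.seed(7)
  for (i in 1:100) {
    Ta <- runif(1, 3, 25)
    tau <- runif(1, 0.04, 0.8) * Ta
    back <- finiteWindowCorrect(closedFormCM(tau, Ta), window = Ta,
                                tol = 1e-5)
    expect_lt(abs(back - tau), 1e-3)
  }
  expect_true(is.na(finiteWindowCorrect(-0.5, window = 6.25)))
})

test_that("centre-of-mass is strictly increasing in tau for noiseless decays", {
  dt <- 25 / 256
  cms <- vapply(seq(0.3, 6, by = 0.3),
                function(tau) centreOfMass(noiselessDecay(tau, dt, 256),
                                           binWidth = dt, window = 12.5),
                numeric(1))
  expect_true(all(diff(cms) > 0))
})

test_that("the pixel chain recovers noiseless lifetimes with a delta IRF", {
  dt <- 25 / 256
  k <- 10                                     # IRF delta in bin 10 (0-based)
  t0 <- (k + 0.5) * dt
  irf <- rep(0, 256); irf[k + 1] <- 1e4
  edges <- (0:256) * dt
  up <- pmax(edges[-1] - t0, 0); lo <- pmax(edges[-257] - t0, 0)
  decay <- 1e5 * (exp(-lo / 2.5) - exp(-up / 2.5))
  tau <- cmmPixel(DecayHistogram(decay, dt), DecayHistogram(irf, dt))
  expect_lt(abs(tau - 2.5) / 2.5, 0.01)
})

test_that("CMM is unbiased with the documented precision on simulated data", {
  cfg <- defaultCfg(ap = 0.05)
  b <- benchmarkEstimator("cmm", cfg, tauGrid = 2.5, nPhotons = 5000,
                          nRepeats = 1024, seed = 100)
  expect_lt(abs(b$deltaTau), 2 * b$sigmaTau / sqrt(b$nValid))
  expect_lt(abs(b$sigmaTau - 0.05), 0.02)     # ~50 ps at N = 5000
  b100 <- benchmarkEstimator("cmm", cfg, tauGrid = 2.5, nPhotons = 100,
                             nRepeats = 1024, seed = 100)
  expect_lt(abs(b100$sigmaTau - 0.3), 0.3 * 0.25)  # ~300 ps at N = 100
})

test_that("adding a uniform offset leaves the recovered lifetime stable", {
  cfg <- defaultCfg()
  h <- simulateDecay(cfg, 2.5, 20000, seed = 55)
  tau0 <- cmmPixel(h, defaultIRF())
  hOff <- DecayHistogram(counts(h) + 10, binWidth(h))
  tauOff <- cmmPixel(hOff, defaultIRF())
  expect_lt(abs(tauOff - tau0), 3 * 2.5 / sqrt(20000))
})

test_that("stack sweeps agree with single-pixel estimates and flag failures", {
  cfg <- simConfig(lifetimeMap = matrix(2.5, 1, 1),
                   photonMap = matrix(2000, 1, 1), afterpulsing = 0.05,
                   seed = 8L)
  stk <- simulateStack(cfg)
  m <- cmmStack(stk, defaultIRF())
  h <- DecayHistogram(cube(stk)[, 1, 1], binWidth(stk))
  expect_equal(lifetimes(m)[1, 1], cmmPixel(h, defaultIRF()))

  # a uniform-lifetime image has no spatial trend in the residuals
  cfgU <- simConfig(lifetimeMap = matrix(2.5, 8, 24),
                    photonMap = matrix(3000, 8, 24), afterpulsing = 0.05,
                    seed = 17L)
  mU <- cmmStack(simulateStack(cfgU), defaultIRF())
  d <- data.frame(tau = as.vector(lifetimes(mU)),
                  col = as.vector(col(lifetimes(mU))))
  fit <- summary(lm(tau ~ col, data = d))
  expect_gt(fit$coefficients["col", "Pr(>|t|)"], 0.01)

  # all-zero stacks are flagged invalid, no error raised
  zero <- FLIMStack(array(0, c(256, 2, 2)), acqWindow = 25)
  mz <- cmmStack(zero, defaultIRF())
  expect_true(all(!validMask(mz)))
  expect_true(all(is.na(lifetimes(mz))))
})
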