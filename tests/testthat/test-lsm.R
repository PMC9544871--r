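# Single-exponential least-squares baseline.

test_that("the fit recovers exact model parameters on noiseless data", {
  dt <- 25 / 256
  irf <- DecayHistogram(c(rep(0, 32), 1000, rep(0, 223)), dt)  # delta IRF
  g <- f3flim:::.binnedIRF(irf, dt, 256)
  y <- 800 * f3flim:::.decayModel(2.2, g, dt)
  f <- lsmFit(DecayHistogram(y, dt), irf)
  expect_true(f$converged)
  expect_equal(f$tau, 2.2, tolerance = 1e-4)
  expect_equal(f$amplitude, 800, tolerance = 1e-3)
  expect_equal(f$background, 0, tolerance = 1e-4)

  # a known constant offset is absorbed by the background term
  f2 <- lsmFit(DecayHistogram(y + 12, dt), irf)
  expect_equal(f2$background, 12, tolerance = 0.12)
  expect_equal(f2$tau, 2.2, tolerance = 1e-3)
})

test_that("rescaling counts rescales amplitude and background, not tau", {
  cfg <- defaultCfg(ap = 0.05)
  h <- simulateDecay(cfg, 2.5, 5000, seed = 61)
  f1 <- lsmFit(h, defaultIRF())
  f3 <- lsmFit(DecayHistogram(counts(h) * 3, binWidth(h)), defaultIRF())
  expect_equal(f3$tau, f1$tau, tolerance = 1e-4)
  expect_equal(f3$amplitude / f1$amplitude, 3, tolerance = 1e-3)
  expect_equal(f3$background / f1$background, 3, tolerance = 1e-2)
})

test_that("least squares is less photon-efficient than CMM with background", {
  cfg <- defaultCfg(ap = 0.05)
  bLSM <- benchmarkEstimator("lsm", cfg, tauGrid = 2.5, nPhotons = 5000,
                             nRepeats = 128, seed = 77)
  bCMM <- benchmarkEstimator("cmm", cfg, tauGrid = 2.5, nPhotons = 5000,
                             nRepeats = 128, seed = 77)
  expect_gt(bLSM$fValue, bCMM$fValue)
})

test_that("stack fitting matches single fits and masks failures", {
  cfg <- simConfig(lifetimeMap = matrix(2.5, 1, 2),
                   photonMap = matrix(3000, 1, 2), afterpulsing = 0.05,
                   seed = 19L)
  stk <- simulateStack(cfg)
  m <- lsmStack(stk, defaultIRF())
  f <- lsmFit(DecayHistogram(cube(stk)[, 1, 1], binWidth(stk)), defaultIRF())
  expect_equal(lifetimes(m)[1, 1], f$tau)

  zero <- FLIMStack(array(0, c(64, 1, 2)), acqWindow = 25)
  mz <- lsmStack(zero, defaultIRF())
  expect_true(all(!validMask(mz)))
})
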