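# Three-window fusion: cut-offs, sigmoid weights, fusion algebra, pilot
# weighting, calibration fit and full-image behaviour.

test_that("lifetime cut-offs follow the crossing formula", {
  A <- 3.218; C <- 0.07339
  expect_equal(lifetimeCutoff(10, 10, A, C), 10 * sqrt(C / A))
  expect_equal(lifetimeCutoff(25, 12.5, A, C), 2.67, tolerance = 0.005)
  expect_equal(lifetimeCutoff(12.5, 6.25, A, C), 1.33, tolerance = 0.005)
  expect_error(lifetimeCutoff(-1, 10, A, C), "> 0")
})

test_that("sigmoid weights behave at the cut-off and in the limits", {
  expect_equal(sigmoidWeight(2.67, 2.67), 0.5)
  expect_equal(sigmoidWeight(1e6, 2.67), 1)
  expect_equal(sigmoidWeight(1e-9, 2.67), 1 / (1 + exp(20)), tolerance = 1e-6)
  expect_equal(sigmoidWeight(2.67 * (1 + 1 / 20), 2.67), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  # saturation without overflow for extreme arguments
  expect_equal(sigmoidWeight(1e9, 1e-3), 1)
  expect_equal(sigmoidWeight(-1e9, 1e-3), 0)
})

test_that("fusion selects the expected window at saturated weights", {
  expect_equal(fuseLifetimes(3, 2.9, 2.5, 1, 1), 3)
  expect_equal(fuseLifetimes(3, 2.9, 2.5, 0, 0), 2.5)
  expect_equal(fuseLifetimes(3, 2.9, 2.5, 0, 1), 2.9)
})

test_that("fusion coefficients always sum to one and stay in range", {
  set.seed(31)
  for (i in 1:200) {
    w12 <- runif(1); w23 <- runif(1, min = w12)   # W23 >= W12 by construction
    coefs <- c(w12, w23 - w12, 1 - w23)
    expect_equal(sum(coefs), 1)
    taus <- sort(runif(3, 0.2, 5), decreasing = TRUE)
    fused <- fuseLifetimes(taus[1], taus[2], taus[3], w12, w23)
    expect_gte(fused, min(taus) - 1e-12)
    expect_lte(fused, max(taus) + 1e-12)
  }
})

test_that("the rational model assigns equal F' to both windows at a cut-off", {
  cal <- defaultCalibration(tauIRF = 3.2)
  fp <- function(tau, Ta) cal@A * tau / Ta + cal@B + cal@C * Ta / tau
  eff <- cal@effWindows
  expect_equal(fp(cal@cutoffs[1], eff[1]), fp(cal@cutoffs[1], eff[2]))
  expect_equal(fp(cal@cutoffs[2], eff[2]), fp(cal@cutoffs[2], eff[3]))
})

test_that("pilot weights route the fusion to the right window", {
  cal <- defaultCalibration(tauIRF = 3.2)
  w <- pilotWeights(cal@cutoffs[1], cal)
  expect_equal(w$W12, 0.5)
  wShort <- pilotWeights(0.4, cal)
  expect_lt(wShort$W12, 1e-6)
  expect_lt(wShort$W23, 1e-3)
  expect_equal(fuseLifetimes(9, 9, 0.4, wShort$W12, wShort$W23), 0.4,
               tolerance = 0.01)
  wLong <- pilotWeights(4.5, cal)
  expect_gt(wLong$W12, 0.99)
  expect_gt(wLong$W23, 0.99)
  expect_equal(fuseLifetimes(4.5, 9, 9, wLong$W12, wLong$W23), 4.5,
               tolerance = 0.05)
  # NA pilots propagate
  expect_true(is.na(pilotWeights(NA_real_, cal)$W12))
})

test_that("calibration parameters are internally consistent", {
  cal <- defaultCalibration(tauIRF = 3.2)
  expect_equal(cal@cutoffs[1],
               sqrt(cal@effWindows[1] * cal@effWindows[2] * cal@C / cal@A))
  expect_error(defaultCalibration(tauIRF = 7), "effective")
  # round trip through the plain-text calibration file
  p <- tempfile(fileext = ".cal")
  writeCalibration(cal, p)
  cal2 <- readCalibration(p)
  expect_equal(cal2@A, cal@A)
  expect_equal(cal2@cutoffs, cal@cutoffs)
})

test_that("a small calibration run yields a sane rational model", {
  cal <- calibrateF3(nRepeats = 96, tauGrid = seq(0.3, 4.5, by = 0.6),
                     seed = 5)
  expect_gt(cal@A, 0)
  expect_gt(cal@C, 0)
  expect_gt(cal@r2, 0.8)
  expect_true(cal@cutoffs[1] > cal@cutoffs[2])
  pts <- cal@provenance$points
  expect_true(all(pts$fPrime >= 0))
})

test_that("fused lifetime maps are unbiased on a uniform image", {
  cfg <- simConfig(lifetimeMap = matrix(2.5, 32, 32),
                   photonMap = matrix(5000, 32, 32), afterpulsing = 0.05,
                   seed = 23L)
  m <- f3cmmStack(simulateStack(cfg), defaultIRF())
  tau <- lifetimes(m)[validMask(m)]
  expect_gte(length(tau), 1000)
  se <- sd(tau) / sqrt(length(tau))
  expect_lt(abs(mean(tau) - 2.5), 2 * se + 0.005)
})

test_that("fusion beats the full window at short lifetimes", {
  cfg <- defaultCfg(ap = 0.05)
  bF3 <- benchmarkEstimator("f3cmm", cfg, tauGrid = 0.5, nPhotons = 5000,
                            nRepeats = 256, seed = 40)
  bCM <- benchmarkEstimator("cmm", cfg, tauGrid = 0.5, nPhotons = 5000,
                            nRepeats = 256, seed = 40)
  expect_lt(bF3$sigmaTau, bCM$sigmaTau)
})
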