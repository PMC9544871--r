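# F3-CMM: CMM at three nested analysis windows fused with lifetime-dependent
# sigmoid weights, plus calibration of the rational F' model that places the
# window cut-offs.

#' Lifetime cut-off between two analysis windows
#'
#' The lifetime at which the rational photon-efficiency curves
#' F'(tau/Ta_i) and F'(tau/Ta_j) of two windows cross:
#' tauC_ij = sqrt(Ta_i * Ta_j * C / A), with Ta the effective window
#' lengths.
#'
#' @param TaI,TaJ effective analysis window lengths in ns (> 0).
#' @param A,C rational-model coefficients (> 0).
#' @return The cut-off lifetime in ns.
#' @examples
#' lifetimeCutoff(25, 12.5, A = 3.218, C = 0.07339)  # ~ 2.67
#' @export
lifetimeCutoff <- function(TaI, TaJ, A, C) {
  if (any(c(TaI, TaJ, A, C) <= 0))
    stop("window lengths and coefficients must be > 0")
  sqrt(TaI * TaJ * C / A)
}

#' Sigmoid blending weight
#'
#' Logistic weight in the relative distance of the lifetime from a cut-off:
#' W = 1 / (1 + exp(-b * (tau - tauC) / tauC)). The exponent is clamped at
#' +/- 700 so the weight saturates to 0/1 without overflow.
#'
#' @param tau lifetime(s) in ns; vectorized.
#' @param tauC cut-off lifetime in ns (> 0).
#' @param b blending factor controlling the transition sharpness
#'   (default 20).
#' @return Weight(s) in [0, 1]; NA inputs propagate.
#' @examples
#' sigmoidWeight(2.67, 2.67)  # 0.5 at the cut-off
#' @export
sigmoidWeight <- function(tau, tauC, b = 20) {
  if (tauC <= 0) stop("tauC must be > 0")
  z <- pmin(pmax(-b * (tau - tauC) / tauC, -700), 700)
  1 / (1 + exp(z))
}

#' Fuse three window lifetimes
#'
#' The weighted combination
#' tau = W12 * tau1 + (W23 - W12) * tau2 + (1 - W23) * tau3,
#' whose coefficients always sum to 1. With W23 >= W12 (guaranteed when both
#' weights share b and tauC12 > tauC23) the result lies within the range of
#' the three inputs.
#'
#' @param tau1,tau2,tau3 lifetimes from the largest, middle and smallest
#'   analysis window (ns); vectorized.
#' @param W12,W23 blending weights in [0, 1].
#' @return Fused lifetime(s) in ns.
#' @examples
#' fuseLifetimes(3, 2.9, 2.5, W12 = 1, W23 = 1)  # tau1
#' @export
fuseLifetimes <- function(tau1, tau2, tau3, W12, W23) {
  W12 * tau1 + (W23 - W12) * tau2 + (1 - W23) * tau3
}

#' Blending weights from the mid-window pilot lifetime
#'
#' The optimal weights depend on the unknown true lifetime; they are
#' estimated from the middle-window CMM lifetime, which is sufficiently
#' accurate and precise around both cut-offs.
#'
#' @param tauMid pilot lifetime(s) from the middle window in ns; NA
#'   propagates.
#' @param calibration a \linkS4class{CalibrationParams}.
#' @return list with elements \code{W12} and \code{W23}.
#' @examples
#' cal <- defaultCalibration(tauIRF = 3.2)
#' pilotWeights(2.5, cal)
#' @export
pilotWeights <- function(tauMid, calibration) {
  stopifnot(is(calibration, "CalibrationParams"))
  list(W12 = sigmoidWeight(tauMid, calibration@cutoffs[1], calibration@b),
       W23 = sigmoidWeight(tauMid, calibration@cutoffs[2], calibration@b))
}

#' Shipped default calibration
#'
#' Calibration parameters built from the published rational-model
#' coefficients A = 3.218 and C = 0.07339 with blending factor b = 20, so
#' that analysis works out of the box; B is not needed by the fusion (only
#' the cut-offs enter) and is set to 0. \code{\link{calibrateF3}}
#' regenerates all coefficients from simulations.
#'
#' @param tauIRF IRF first moment in ns used to derive effective window
#'   lengths (default 3.2, the default simulated IRF centre).
#' @param windows three decreasing total analysis window lengths in ns.
#' @param b blending factor (default 20).
#' @return A \linkS4class{CalibrationParams}.
#' @examples
#' defaultCalibration(tauIRF = 3.2)
#' @export
defaultCalibration <- function(tauIRF = 3.2, windows = c(25, 12.5, 6.25),
                               b = 20) {
  A <- 3.218; C <- 0.07339
  eff <- windows - tauIRF
  if (any(eff <= 0)) stop("tauIRF leaves a non-positive effective window")
  .makeCalibration(A = A, B = 0, C = C, b = b, windows = windows,
      effWindows = eff,
      cutoffs = c(lifetimeCutoff(eff[1], eff[2], A, C),
                  lifetimeCutoff(eff[2], eff[3], A, C)),
      provenance = list(source = "published coefficients"))
}

#' F3-CMM lifetime map of a FLIM stack
#'
#' Runs \code{\link{cmmStack}} at the three analysis windows, evaluates the
#' blending weights at the middle-window pilot lifetime, and fuses the three
#' maps per pixel. If the middle-window estimate of a pixel is invalid the
#' largest-window estimate is used as the pilot; pixels invalid in every
#' window remain invalid.
#'
#' @param stack a \linkS4class{FLIMStack}.
#' @param irf an \linkS4class{IRFModel} or measured IRF histogram.
#' @param calibration a \linkS4class{CalibrationParams}; default
#'   \code{\link{defaultCalibration}} with tauIRF taken from the IRF.
#' @param nPreBins,nIter,background passed to \code{\link{cmmStack}}.
#' @return A \linkS4class{LifetimeMap} with method \code{"f3cmm"}.
#' @examples
#' cfg <- simConfig(lifetimeMap = matrix(2.5, 2, 2),
#'                  photonMap = matrix(2000, 2, 2), afterpulsing = 0.05)
#' f3cmmStack(simulateStack(cfg), gaussianIRF(3.2, 0.15))
#' @export
f3cmmStack <- function(stack, irf, calibration = NULL, nPreBins = 20,
                       nIter = 10, background = c("global", "pixel")) {
  stopifnot(is(stack, "FLIMStack"))
  background <- match.arg(background)
  if (is(irf, "DecayHistogram")) irf <- measuredIRF(irf)
  tauIRF <- irfMoment(irf, binWidth = binWidth(stack), nBins = nBins(stack))
  if (is.null(calibration)) calibration <- defaultCalibration(tauIRF = tauIRF)
  wins <- calibration@windows
  if (wins[1] > stack@acqWindow + 1e-9)
    stop("largest analysis window exceeds the acquisition window")
  maps <- lapply(wins, function(w)
    cmmStack(stack, irf, window = w, nPreBins = nPreBins, nIter = nIter,
             background = background))
  t1 <- maps[[1]]@tau; t2 <- maps[[2]]@tau; t3 <- maps[[3]]@tau
  pilot <- t2
  useT1 <- !is.finite(pilot) & is.finite(t1)
  pilot[useT1] <- t1[useT1]
  w <- pilotWeights(pilot, calibration)
  fused <- fuseLifetimes(t1, t2, t3, w$W12, w$W23)
  # weights saturate, so windows with weight ~0 may be invalid harmlessly:
  # fall back to the pilot estimate when the fusion touches an invalid input
  onlyPilot <- !is.finite(fused) & is.finite(pilot)
  fused[onlyPilot] <- pilot[onlyPilot]
  valid <- is.finite(fused)
  fused[!valid] <- NA_real_
  new("LifetimeMap", tau = fused, intensity = maps[[1]]@intensity,
      valid = valid, window = wins, method = "f3cmm")
}

#' Calibrate the rational F' model from simulations
#'
#' Reproduces the window-calibration study: for each of the three analysis
#' windows, repeated decays are simulated over a lifetime grid, the CMM
#' lifetime is estimated (background level pooled over the repeats, as for
#' an image), and the photon efficiency F' is computed per grid point. For
#' this windowed study N is the expected signal photon number inside the
#' effective analysis window, N * (1 - exp(-Ta/tau)): a short window only
#' ever sees part of the decay, and the efficiency of the windowed
#' estimator is judged against the photons available to it. The pooled
#' (alpha, F') points, with alpha = lifetime / effective window length
#' restricted to the model's validity span, are fitted by ordinary least
#' squares to F'(alpha) = A*alpha + B + C/alpha, and the lifetime cut-offs
#' are derived from the fitted A and C.
#'
#' @param cfg a \linkS4class{SimConfig} template for the acquisition
#'   parameters (its maps are ignored).
#' @param windows three decreasing total analysis window lengths in ns.
#' @param tauGrid lifetime grid in ns (default 0.3 to 4.5 by 0.3, the
#'   bundled simulation-study grid).
#' @param nPhotons signal photons per decay (default 5000).
#' @param nRepeats repeats per grid point (default 1024).
#' @param alphaRange validity span of alpha kept for the fit
#'   (default c(0, 0.7)).
#' @param b blending factor carried into the result (default 20).
#' @param seed integer seed.
#' @return A \linkS4class{CalibrationParams} with fitted A, B, C, the
#'   derived cut-offs, the fit R^2 and provenance (including the pooled
#'   fit table as a data.frame).
#' @export
calibrateF3 <- function(cfg = simConfig(afterpulsing = 0.05),
                        windows = c(25, 12.5, 6.25),
                        tauGrid = seq(0.3, 4.5, by = 0.3),
                        nPhotons = 5000, nRepeats = 1024,
                        alphaRange = c(0, 0.7), b = 20, seed = 1L) {
  stopifnot(is(cfg, "SimConfig"))
  if (any(diff(windows) >= 0) || length(windows) != 3L)
    stop("need three strictly decreasing windows")
  irf <- gaussianIRF(cfg@irfCentre, cfg@irfSigma)
  dt <- binWidth(cfg); nb <- cfg@nBins
  tauIRF <- irfMoment(irf, binWidth = dt, nBins = nb)
  eff <- windows - tauIRF
  if (any(eff <= 0)) stop("IRF moment leaves a non-positive effective window")
  rows <- list()
  for (g in seq_along(tauGrid)) {
    tau <- tauGrid[g]
    M <- .simulateRepeats(cfg, tau, nPhotons, nRepeats,
                          seed = .pixelSeed(seed, g, 0L))
    npre <- .preBins(rowSums(M), 20)
    bg <- mean(M[seq_len(npre), ])
    for (wi in seq_along(windows)) {
      est <- .cmmMatrix(M, dt, windows[wi], tauIRF, background = bg,
                        nIter = 200)
      est <- est[is.finite(est)]
      if (length(est) < 2L) next
      dTau <- mean(est) - tau
      sTau <- stats::sd(est)
      nWindow <- nPhotons * (1 - exp(-eff[wi] / tau))
      rows[[length(rows) + 1L]] <- data.frame(
        tau = tau, window = windows[wi], alpha = tau / eff[wi],
        nWindow = nWindow, deltaTau = dTau, sigmaTau = sTau,
        fPrime = fPrime(nWindow, sTau, dTau, tau))
    }
  }
  pts <- do.call(rbind, rows)
  fitPts <- pts[pts$alpha >= alphaRange[1] & pts$alpha <= alphaRange[2], ]
  if (nrow(fitPts) < 4L) stop("too few calibration points for the fit")
  fit <- stats::lm(fPrime ~ alpha + I(1 / alpha), data = fitPts)
  cf <- stats::coef(fit)
  A <- unname(cf["alpha"]); B <- unname(cf["(Intercept)"])
  C <- unname(cf["I(1/alpha)"])
  if (!is.finite(A) || !is.finite(C) || A <= 0 || C <= 0)
    stop("calibration fit failed: non-positive A or C")
  .makeCalibration(A = A, B = B, C = C, b = b, windows = windows,
      effWindows = eff,
      cutoffs = c(lifetimeCutoff(eff[1], eff[2], A, C),
                  lifetimeCutoff(eff[2], eff[3], A, C)),
      r2 = summary(fit)$r.squared,
      provenance = list(seed = seed, nRepeats = nRepeats,
        nPhotons = nPhotons, afterpulsing = cfg@afterpulsing,
        tauGrid = tauGrid, alphaRange = alphaRange, points = pts))
}
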