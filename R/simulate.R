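# Monte-Carlo TCSPC simulator: inverse-CPDF sampling of photon emission and
# excitation times, laser-period wrap-around, uniform after-pulsing background.

#' Sample photon emission times
#'
#' Draws exponential emission delays by inverse-transform sampling of the
#' cumulative distribution 1 - exp(-t/tau) on uniform variates.
#'
#' @param n number of photons (>= 0).
#' @param tau fluorescence lifetime in ns (> 0).
#' @param seed optional integer seed; when given the RNG is seeded first.
#' @return numeric vector of n emission times in ns.
#' @examples
#' mean(sampleEmissionTimes(1e5, 2.5, seed = 1))  # ~ 2.5
#' @export
sampleEmissionTimes <- function(n, tau, seed = NULL) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  if (n < 0) stop("n must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  -tau * log1p(-stats::runif(n))
}

#' Sample photon excitation times
#'
#' Draws Gaussian excitation times (the IRF) by inverse-CPDF sampling:
#' the Gaussian quantile function applied to uniform variates. sigma = 0
#' degenerates to the constant t0.
#'
#' @param n number of photons (>= 0).
#' @param t0 IRF centre in ns.
#' @param sigma IRF standard deviation in ns (>= 0).
#' @param seed optional integer seed.
#' @return numeric vector of n excitation times in ns.
#' @examples
#' sampleExcitationTimes(3, 3.2, 0)  # all 3.2
#' @export
sampleExcitationTimes <- function(n, t0, sigma, seed = NULL) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (n < 0) stop("n must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  if (sigma == 0) return(rep(t0, n))
  stats::qnorm(stats::runif(n), mean = t0, sd = sigma)
}

# Bin arrival times into the acquisition window. Times are wrapped modulo the
# laser period; with period > T, photons landing in [T, period) fall outside
# the recorded window and are dropped.
.binArrivalTimes <- function(t, acqWindow, nBins, period) {
  t <- t %% period
  t <- t[t < acqWindow]
  dt <- acqWindow / nBins
  idx <- floor(t / dt) + 1L
  idx[idx > nBins] <- nBins  # guard t == acqWindow after rounding
  tabulate(idx, nbins = nBins)
}

#' Simulate one TCSPC decay
#'
#' Draws \code{nPhotons} arrival times as emission + excitation time, wraps
#' them modulo the laser period, adds \code{round(Ap * nPhotons)} background
#' photons uniform on [0, T), and bins everything into the acquisition
#' window.
#'
#' @param cfg a \linkS4class{SimConfig} providing the acquisition parameters.
#' @param tau true lifetime in ns (> 0).
#' @param nPhotons signal photon count (>= 0).
#' @param seed optional integer seed.
#' @return A \linkS4class{DecayHistogram}.
#' @examples
#' cfg <- simConfig()
#' h <- simulateDecay(cfg, tau = 2.5, nPhotons = 5000, seed = 1)
#' @export
simulateDecay <- function(cfg, tau, nPhotons, seed = NULL) {
  stopifnot(is(cfg, "SimConfig"))
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  if (nPhotons < 0) stop("nPhotons must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  period <- 1000 / cfg@repRate
  tem <- sampleEmissionTimes(nPhotons, tau)
  tex <- sampleExcitationTimes(nPhotons, cfg@irfCentre, cfg@irfSigma)
  nBkg <- round(cfg@afterpulsing * nPhotons)
  tBkg <- stats::runif(nBkg) * cfg@acqWindow
  cnt <- .binArrivalTimes(c(tem + tex, tBkg), cfg@acqWindow, cfg@nBins, period)
  DecayHistogram(cnt, binWidth = cfg@acqWindow / cfg@nBins)
}

#' Simulate a measured IRF decay
#'
#' The IRF histogram is obtained by setting all emission times to zero, so
#' the recorded arrival times are excitation times only.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param nPhotons number of photons (>= 0).
#' @param seed optional integer seed.
#' @return A \linkS4class{DecayHistogram} of the IRF.
#' @export
simulateIRF <- function(cfg, nPhotons, seed = NULL) {
  stopifnot(is(cfg, "SimConfig"))
  if (nPhotons < 0) stop("nPhotons must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  period <- 1000 / cfg@repRate
  tex <- sampleExcitationTimes(nPhotons, cfg@irfCentre, cfg@irfSigma)
  DecayHistogram(.binArrivalTimes(tex, cfg@acqWindow, cfg@nBins, period),
                 binWidth = cfg@acqWindow / cfg@nBins)
}

# Deterministic per-pixel seed: a multiplicative-congruential mix of the
# global seed with the pixel coordinates, kept below 2^31 - 1. Exact in
# double arithmetic (intermediates < 2^53).
.pixelSeed <- function(seed, row, col) {
  h <- seed %% 2147483647
  h <- (h * 69069 + row) %% 2147483647
  h <- (h * 69069 + col) %% 2147483647
  as.integer(h)
}

#' Simulate a FLIM image stack
#'
#' Runs \code{\link{simulateDecay}} independently for every pixel of the
#' configured lifetime and photon maps. Pixel seeds are derived
#' deterministically from the global seed and the pixel coordinates, so
#' stacks are bit-reproducible and any sub-image equals the corresponding
#' single-pixel simulations.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return A \linkS4class{FLIMStack} with ground-truth maps attached.
#' @examples
#' cfg <- simConfig(lifetimeMap = matrix(2.5, 2, 3),
#'                  photonMap = matrix(500, 2, 3), seed = 7)
#' stk <- simulateStack(cfg)
#' @export
simulateStack <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  nr <- nrow(cfg@lifetimeMap); nc <- ncol(cfg@lifetimeMap)
  cube <- array(0, dim = c(cfg@nBins, nr, nc))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      h <- simulateDecay(cfg, cfg@lifetimeMap[i, j], cfg@photonMap[i, j],
                         seed = .pixelSeed(cfg@seed, i, j))
      cube[, i, j] <- h@counts
    }
  }
  FLIMStack(cube, acqWindow = cfg@acqWindow, repRate = cfg@repRate,
            afterpulsing = cfg@afterpulsing, lifetimeMap = cfg@lifetimeMap,
            photonMap = cfg@photonMap, seed = cfg@seed)
}

# Fast batch simulation of repeated decays under identical conditions.
# Returns an nBins x nRepeats count matrix; used by the benchmark harness
# and the calibration study, where thousands of repeats are needed.
.simulateRepeats <- function(cfg, tau, nPhotons, nRepeats, seed) {
  set.seed(seed)
  period <- 1000 / cfg@repRate
  nb <- cfg@nBins
  out <- matrix(0L, nb, nRepeats)
  nBkg <- round(cfg@afterpulsing * nPhotons)
  for (r in seq_len(nRepeats)) {
    tem <- sampleEmissionTimes(nPhotons, tau)
    tex <- sampleExcitationTimes(nPhotons, cfg@irfCentre, cfg@irfSigma)
    tBkg <- stats::runif(nBkg) * cfg@acqWindow
    out[, r] <- .binArrivalTimes(c(tem + tex, tBkg), cfg@acqWindow, nb, period)
  }
  out
}
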