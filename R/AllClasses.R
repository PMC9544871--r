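#' @import methods
NULL

#' DecayHistogram: a binned TCSPC decay for one pixel
#'
#' Photon counts over uniform time bins, together with the bin geometry.
#' Bins are half-open intervals \code{[k*binWidth, (k+1)*binWidth)} for
#' \code{k = 0, ..., nBins-1}, anchored at \code{tStart} (0 by convention).
#' Counts are non-negative on construction; background-corrected decays are
#' plain numeric vectors, not \code{DecayHistogram} objects.
#'
#' @slot counts numeric vector of non-negative photon counts, one per bin.
#' @slot binWidth bin width in ns.
#' @slot tStart left edge of bin 0 in ns.
#' @export
setClass("DecayHistogram",
  representation(counts = "numeric", binWidth = "numeric", tStart = "numeric"),
  prototype(tStart = 0))

setValidity("DecayHistogram", function(object) {
  msg <- NULL
  if (length(object@counts) < 2L)
    msg <- c(msg, "need at least 2 time bins")
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "counts must be finite and non-negative")
  if (length(object@binWidth) != 1L || !is.finite(object@binWidth) ||
      object@binWidth <= 0)
    msg <- c(msg, "binWidth must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Construct a DecayHistogram
#'
#' @param counts non-negative photon counts per bin.
#' @param binWidth bin width in ns.
#' @param tStart left edge of the first bin in ns (default 0).
#' @return A \linkS4class{DecayHistogram}.
#' @examples
#' h <- DecayHistogram(c(0, 5, 3, 1), binWidth = 0.1)
#' totalCounts(h)
#' @export
DecayHistogram <- function(counts, binWidth, tStart = 0) {
  new("DecayHistogram", counts = as.numeric(counts),
      binWidth = as.numeric(binWidth), tStart = as.numeric(tStart))
}

#' IRFModel: instrument response function
#'
#' Either Gaussian parameters (centre \code{t0}, standard deviation
#' \code{sigma}, both ns), a measured IRF histogram, or both. The temporal
#' first moment used for lifetime correction is computed by
#' \code{\link{irfMoment}}.
#'
#' @slot t0 Gaussian IRF centre in ns (NA if only a measured histogram).
#' @slot sigma Gaussian IRF standard deviation in ns (NA if measured only).
#' @slot histogram a \linkS4class{DecayHistogram} of a measured IRF, or NULL.
#' @export
setClass("IRFModel",
  representation(t0 = "numeric", sigma = "numeric", histogram = "ANY"),
  prototype(t0 = NA_real_, sigma = NA_real_, histogram = NULL))

setValidity("IRFModel", function(object) {
  msg <- NULL
  gaussOK <- is.finite(object@t0) && is.finite(object@sigma) &&
    object@sigma >= 0
  measOK <- is(object@histogram, "DecayHistogram")
  if (!gaussOK && !measOK)
    msg <- c(msg, "need Gaussian parameters (t0, sigma >= 0) or a measured histogram")
  if (is.finite(object@sigma) && object@sigma < 0)
    msg <- c(msg, "sigma must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Gaussian IRF model
#'
#' @param t0 centre of the Gaussian IRF in ns.
#' @param sigma standard deviation of the Gaussian IRF in ns (>= 0).
#' @return An \linkS4class{IRFModel}.
#' @examples
#' irf <- gaussianIRF(3.2, 0.15)
#' @export
gaussianIRF <- function(t0, sigma) {
  if (!is.finite(sigma) || sigma < 0)
    stop("sigma must be a non-negative number")
  new("IRFModel", t0 = as.numeric(t0), sigma = as.numeric(sigma))
}

#' Measured IRF model
#'
#' @param histogram a \linkS4class{DecayHistogram} of the measured IRF.
#' @return An \linkS4class{IRFModel}.
#' @export
measuredIRF <- function(histogram) {
  stopifnot(is(histogram, "DecayHistogram"))
  new("IRFModel", histogram = histogram)
}

#' SimConfig: Monte-Carlo TCSPC simulation configuration
#'
#' Per-pixel ground truth (lifetime and signal photon maps) plus acquisition
#' parameters for the TCSPC simulator. The bin width is exactly
#' \code{acqWindow / nBins}; the laser period is \code{1000 / repRate} ns.
#'
#' @slot lifetimeMap matrix of true lifetimes per pixel (ns, all > 0).
#' @slot photonMap matrix of signal photon counts per pixel (>= 0).
#' @slot afterpulsing after-pulsing fraction Ap >= 0: the number of
#'   uniformly-distributed background photons is \code{round(Ap * N)}.
#' @slot acqWindow acquisition window T in ns.
#' @slot nBins number of time bins.
#' @slot irfCentre Gaussian IRF centre t0 in ns.
#' @slot irfSigma Gaussian IRF standard deviation in ns.
#' @slot repRate laser repetition rate in MHz.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
  representation(lifetimeMap = "matrix", photonMap = "matrix",
    afterpulsing = "numeric", acqWindow = "numeric", nBins = "integer",
    irfCentre = "numeric", irfSigma = "numeric", repRate = "numeric",
    seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- NULL
  if (!identical(dim(object@lifetimeMap), dim(object@photonMap)))
    msg <- c(msg, "lifetimeMap and photonMap must have the same shape")
  if (any(!is.finite(object@lifetimeMap)) || any(object@lifetimeMap <= 0))
    msg <- c(msg, "all lifetimes must be positive")
  if (any(!is.finite(object@photonMap)) || any(object@photonMap < 0))
    msg <- c(msg, "all photon counts must be >= 0")
  if (object@afterpulsing < 0)
    msg <- c(msg, "afterpulsing must be >= 0")
  if (object@nBins < 2L)
    msg <- c(msg, "nBins must be >= 2")
  if (object@acqWindow <= 0)
    msg <- c(msg, "acqWindow must be > 0")
  if (object@irfSigma < 0)
    msg <- c(msg, "irfSigma must be >= 0")
  if (1000 / object@repRate < object@acqWindow / object@nBins)
    msg <- c(msg, "laser period must be >= bin width")
  if (is.null(msg)) TRUE else msg
})

#' Construct a simulation configuration
#'
#' Defaults are the typical TCSPC acquisition conditions used throughout the
#' bundled simulation studies: T = 25 ns, 256 bins, Gaussian IRF centred at
#' 3.2 ns with 150 ps standard deviation, 20 MHz repetition rate.
#'
#' @param lifetimeMap matrix (or scalar) of true lifetimes in ns.
#' @param photonMap matrix (or scalar) of signal photon counts.
#' @param afterpulsing after-pulsing fraction Ap (default 0).
#' @param acqWindow acquisition window T in ns (default 25).
#' @param nBins number of time bins (default 256).
#' @param irfCentre Gaussian IRF centre in ns (default 3.2).
#' @param irfSigma Gaussian IRF standard deviation in ns (default 0.15).
#' @param repRate laser repetition rate in MHz (default 20).
#' @param seed integer RNG seed (default 1).
#' @return A \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(lifetimeMap = 2.5, photonMap = 5000, afterpulsing = 0.05)
#' @export
simConfig <- function(lifetimeMap = 2.5, photonMap = 1000, afterpulsing = 0,
                      acqWindow = 25, nBins = 256L, irfCentre = 3.2,
                      irfSigma = 0.15, repRate = 20, seed = 1L) {
  if (!is.matrix(lifetimeMap)) lifetimeMap <- matrix(lifetimeMap, 1, 1)
  if (!is.matrix(photonMap))
    photonMap <- matrix(photonMap, nrow(lifetimeMap), ncol(lifetimeMap))
  new("SimConfig", lifetimeMap = lifetimeMap, photonMap = photonMap,
      afterpulsing = afterpulsing, acqWindow = acqWindow,
      nBins = as.integer(nBins), irfCentre = irfCentre, irfSigma = irfSigma,
      repRate = repRate, seed = as.integer(seed))
}

#' FLIMStack: a 3-D FLIM data cube
#'
#' Photon counts indexed (bin, row, col) with acquisition metadata and,
#' for simulated stacks, the ground-truth lifetime and photon maps.
#'
#' @slot cube 3-D array of counts, dim = c(nBins, nrow, ncol).
#' @slot acqWindow acquisition window T in ns.
#' @slot repRate laser repetition rate in MHz.
#' @slot afterpulsing after-pulsing fraction used in simulation (NA if unknown).
#' @slot lifetimeMap ground-truth lifetime matrix or NULL.
#' @slot photonMap ground-truth signal photon matrix or NULL.
#' @slot seed simulation seed (NA if not simulated).
#' @export
setClass("FLIMStack",
  representation(cube = "array", acqWindow = "numeric", repRate = "numeric",
    afterpulsing = "numeric", lifetimeMap = "ANY", photonMap = "ANY",
    seed = "numeric"),
  prototype(afterpulsing = NA_real_, lifetimeMap = NULL, photonMap = NULL,
    seed = NA_real_, repRate = 20))

setValidity("FLIMStack", function(object) {
  msg <- NULL
  if (length(dim(object@cube)) != 3L)
    msg <- c(msg, "cube must be a 3-D array (bin, row, col)")
  if (any(!is.finite(object@cube)) || any(object@cube < 0))
    msg <- c(msg, "cube entries must be finite and >= 0")
  if (object@acqWindow <= 0)
    msg <- c(msg, "acqWindow must be > 0")
  if (!is.null(object@lifetimeMap) &&
      !identical(dim(object@lifetimeMap), dim(object@cube)[2:3]))
    msg <- c(msg, "lifetimeMap shape must match the image plane")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FLIMStack
#'
#' @param cube 3-D count array, dim = c(nBins, nrow, ncol).
#' @param acqWindow acquisition window T in ns.
#' @param repRate laser repetition rate in MHz.
#' @param afterpulsing after-pulsing fraction (NA if unknown).
#' @param lifetimeMap,photonMap optional ground-truth matrices.
#' @param seed simulation seed (NA if not simulated).
#' @return A \linkS4class{FLIMStack}.
#' @export
FLIMStack <- function(cube, acqWindow, repRate = 20, afterpulsing = NA_real_,
                      lifetimeMap = NULL, photonMap = NULL, seed = NA_real_) {
  new("FLIMStack", cube = cube, acqWindow = acqWindow, repRate = repRate,
      afterpulsing = afterpulsing, lifetimeMap = lifetimeMap,
      photonMap = photonMap, seed = as.numeric(seed))
}

#' AnalysisWindow: the temporal window of the centre-of-mass sums
#'
#' The analysis window is \code{[0, length]} on the acquisition time axis.
#' The effective window used by the finite-window correction is
#' \code{length - tauIRF}, because the decay only starts at the temporal
#' position of the IRF.
#'
#' @slot length total analysis window length in ns.
#' @slot effectiveLength length minus the IRF first moment, in ns.
#' @export
setClass("AnalysisWindow",
  representation(length = "numeric", effectiveLength = "numeric"))

setValidity("AnalysisWindow", function(object) {
  msg <- NULL
  if (object@length <= 0) msg <- c(msg, "window length must be > 0")
  if (object@effectiveLength <= 0)
    msg <- c(msg, "effective window length must be > 0 after IRF subtraction")
  if (object@effectiveLength > object@length)
    msg <- c(msg, "effective length cannot exceed total length")
  if (is.null(msg)) TRUE else msg
})

#' Construct an analysis window
#'
#' @param length total window length in ns (window is [0, length]).
#' @param tauIRF first moment of the IRF in ns, subtracted to obtain the
#'   effective length (default 0).
#' @return An \linkS4class{AnalysisWindow}.
#' @examples
#' analysisWindow(25, tauIRF = 3.2)
#' @export
analysisWindow <- function(length, tauIRF = 0) {
  new("AnalysisWindow", length = as.numeric(length),
      effectiveLength = as.numeric(length - tauIRF))
}

#' CalibrationParams: rational F'-model coefficients and window cut-offs
#'
#' Coefficients of the rational photon-efficiency model
#' F'(alpha) = A*alpha + B + C/alpha with alpha = lifetime / effective
#' analysis window, the sigmoid blending factor b, the three analysis
#' windows, and the derived lifetime cut-offs
#' tau_c_ij = sqrt(Ta_i * Ta_j * C / A).
#'
#' @slot A,B,C rational-model coefficients (A > 0, C > 0; B may be any value).
#' @slot b sigmoid blending factor (> 0).
#' @slot windows total lengths of the three analysis windows, decreasing (ns).
#' @slot effWindows effective lengths (total minus tauIRF), decreasing (ns).
#' @slot cutoffs lifetime cut-offs c(tauC12, tauC23) in ns.
#' @slot r2 goodness of fit of the rational model (NA for shipped defaults).
#' @slot provenance list with fit provenance (seed, repeats, grid, ...).
#' @export
setClass("CalibrationParams",
  representation(A = "numeric", B = "numeric", C = "numeric", b = "numeric",
    windows = "numeric", effWindows = "numeric", cutoffs = "numeric",
    r2 = "numeric", provenance = "list"),
  prototype(A = 3.218, B = 0, C = 0.07339, b = 20,
    windows = c(25, 12.5, 6.25), effWindows = c(25, 12.5, 6.25),
    cutoffs = c(sqrt(25 * 12.5 * 0.07339 / 3.218),
                sqrt(12.5 * 6.25 * 0.07339 / 3.218)),
    r2 = NA_real_, provenance = list()))

# Constructor that avoids partial matching of the slot name "C" against
# new()'s formal argument "Class": fill slots on a valid prototype, then
# run the validity check once.
.makeCalibration <- function(A, B, C, b, windows, effWindows, cutoffs,
                             r2 = NA_real_, provenance = list()) {
  obj <- new("CalibrationParams")
  obj@A <- as.numeric(A); obj@B <- as.numeric(B); obj@C <- as.numeric(C)
  obj@b <- as.numeric(b)
  obj@windows <- as.numeric(windows)
  obj@effWindows <- as.numeric(effWindows)
  obj@cutoffs <- as.numeric(cutoffs)
  obj@r2 <- as.numeric(r2)
  obj@provenance <- provenance
  validObject(obj)
  obj
}

setValidity("CalibrationParams", function(object) {
  msg <- NULL
  if (object@A <= 0 || object@C <= 0)
    msg <- c(msg, "A and C must be > 0")
  if (object@b <= 0) msg <- c(msg, "b must be > 0")
  if (length(object@windows) != 3L || any(diff(object@windows) >= 0))
    msg <- c(msg, "need three strictly decreasing windows")
  if (length(object@effWindows) != 3L || any(object@effWindows <= 0))
    msg <- c(msg, "effective window lengths must be positive")
  if (length(object@cutoffs) != 2L || any(object@cutoffs <= 0) ||
      diff(object@cutoffs) >= 0)
    msg <- c(msg, "cutoffs must satisfy tauC12 > tauC23 > 0")
  ratio <- sqrt(object@C / object@A)
  expect <- c(sqrt(object@effWindows[1] * object@effWindows[2]),
              sqrt(object@effWindows[2] * object@effWindows[3])) * ratio
  if (any(abs(object@cutoffs - expect) > 1e-8 * expect))
    msg <- c(msg, "cutoffs inconsistent with A, C and effective windows")
  if (is.null(msg)) TRUE else msg
})

#' LifetimeMap: a per-pixel lifetime image
#'
#' @slot tau matrix of lifetimes in ns (NA where invalid).
#' @slot intensity matrix of total counts per pixel.
#' @slot valid logical matrix flagging pixels with a usable estimate.
#' @slot window total analysis window length(s) in ns that produced the map
#'   (three values for F3-CMM).
#' @slot method estimator name ("cmm", "f3cmm" or "lsm").
#' @export
setClass("LifetimeMap",
  representation(tau = "matrix", intensity = "matrix", valid = "matrix",
    window = "numeric", method = "character"))

setValidity("LifetimeMap", function(object) {
  msg <- NULL
  if (!identical(dim(object@tau), dim(object@intensity)) ||
      !identical(dim(object@tau), dim(object@valid)))
    msg <- c(msg, "tau, intensity and valid must have identical shape")
  if (any(object@intensity < 0, na.rm = TRUE))
    msg <- c(msg, "intensity must be >= 0")
  if (any(is.finite(object@tau[!object@valid])))
    msg <- c(msg, "invalid pixels must carry NA lifetimes")
  if (is.null(msg)) TRUE else msg
})
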