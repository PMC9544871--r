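# Accessor generics and show methods

#' Number of time bins
#' @param x a DecayHistogram, FLIMStack or SimConfig.
#' @return integer bin count.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Bin width in ns
#' @param x a DecayHistogram, FLIMStack or SimConfig.
#' @return bin width in ns.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' Acquisition window length in ns
#' @param x a FLIMStack or SimConfig.
#' @return window length T in ns.
#' @export
setGeneric("acqWindow", function(x) standardGeneric("acqWindow"))

#' Photon counts
#' @param x a DecayHistogram.
#' @return numeric vector of per-bin counts.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' Total photon count
#' @param x a DecayHistogram.
#' @return total number of counts.
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))

#' Count cube of a FLIM stack
#' @param x a FLIMStack.
#' @return 3-D array (bin, row, col).
#' @export
setGeneric("cube", function(x) standardGeneric("cube"))

#' Per-pixel lifetimes of a LifetimeMap
#' @param x a LifetimeMap.
#' @return matrix of lifetimes in ns, NA where invalid.
#' @export
setGeneric("lifetimes", function(x) standardGeneric("lifetimes"))

#' Per-pixel total intensity of a LifetimeMap
#' @param x a LifetimeMap.
#' @return matrix of total counts.
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' Validity mask of a LifetimeMap
#' @param x a LifetimeMap.
#' @return logical matrix, TRUE where the lifetime estimate is usable.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' First temporal moment of an IRF
#'
#' Applies the discrete centre-of-mass estimator to the IRF. For a measured
#' IRF the histogram itself is used; for a Gaussian model the expected binned
#' histogram on the requested geometry is used, so both routes share one
#' convention. The moment of a narrow Gaussian IRF equals its centre t0 (up
#' to binning error), and of a delta IRF in bin k equals the bin midpoint
#' (k + 1/2) * binWidth.
#'
#' @param irf an \linkS4class{IRFModel} or \linkS4class{DecayHistogram}.
#' @param binWidth bin width in ns (required for a Gaussian model).
#' @param nBins number of bins (required for a Gaussian model).
#' @param window optional \linkS4class{AnalysisWindow}; default full axis.
#' @return the IRF first moment tauIRF in ns.
#' @examples
#' irfMoment(gaussianIRF(3.2, 0.15), binWidth = 25 / 256, nBins = 256)
#' @export
setGeneric("irfMoment",
  function(irf, binWidth = NULL, nBins = NULL, window = NULL)
    standardGeneric("irfMoment"))

#' @rdname nBins
setMethod("nBins", "DecayHistogram", function(x) length(x@counts))
#' @rdname nBins
setMethod("nBins", "FLIMStack", function(x) dim(x@cube)[1L])
#' @rdname nBins
setMethod("nBins", "SimConfig", function(x) x@nBins)

#' @rdname binWidth
setMethod("binWidth", "DecayHistogram", function(x) x@binWidth)
#' @rdname binWidth
setMethod("binWidth", "FLIMStack", function(x) x@acqWindow / dim(x@cube)[1L])
#' @rdname binWidth
setMethod("binWidth", "SimConfig", function(x) x@acqWindow / x@nBins)

#' @rdname acqWindow
setMethod("acqWindow", "FLIMStack", function(x) x@acqWindow)
#' @rdname acqWindow
setMethod("acqWindow", "SimConfig", function(x) x@acqWindow)

#' @rdname counts
setMethod("counts", "DecayHistogram", function(x) x@counts)
#' @rdname totalCounts
setMethod("totalCounts", "DecayHistogram", function(x) sum(x@counts))

#' @rdname cube
setMethod("cube", "FLIMStack", function(x) x@cube)

#' @rdname lifetimes
setMethod("lifetimes", "LifetimeMap", function(x) x@tau)
#' @rdname intensity
setMethod("intensity", "LifetimeMap", function(x) x@intensity)
#' @rdname validMask
setMethod("validMask", "LifetimeMap", function(x) x@valid)

setMethod("show", "DecayHistogram", function(object) {
  cat("DecayHistogram:", length(object@counts), "bins of",
      signif(object@binWidth, 4), "ns,", sum(object@counts), "counts\n")
})

setMethod("show", "FLIMStack", function(object) {
  d <- dim(object@cube)
  cat("FLIMStack:", d[2], "x", d[3], "pixels,", d[1], "time bins,",
      "T =", object@acqWindow, "ns, repRate =", object@repRate, "MHz\n")
  if (!is.null(object@lifetimeMap))
    cat("  ground truth attached (lifetime range ",
        paste(signif(range(object@lifetimeMap), 3), collapse = "-"),
        " ns)\n", sep = "")
})

setMethod("show", "LifetimeMap", function(object) {
  cat("LifetimeMap (", object@method, "): ", nrow(object@tau), " x ",
      ncol(object@tau), " pixels, ", sum(object@valid), " valid; window ",
      paste(object@window, collapse = "/"), " ns\n", sep = "")
  if (any(object@valid))
    cat("  lifetime range",
        paste(signif(range(object@tau[object@valid]), 3), collapse = " - "),
        "ns\n")
})

setMethod("show", "CalibrationParams", function(object) {
  cat("CalibrationParams: A =", signif(object@A, 4),
      "B =", signif(object@B, 4), "C =", signif(object@C, 4),
      "b =", object@b, "\n  windows:",
      paste(object@windows, collapse = "/"), "ns (effective",
      paste(signif(object@effWindows, 4), collapse = "/"),
      "ns)\n  cutoffs: tauC12 =", signif(object@cutoffs[1], 4),
      "ns, tauC23 =", signif(object@cutoffs[2], 4), "ns\n")
  if (is.finite(object@r2)) cat("  fit R^2 =", signif(object@r2, 5), "\n")
})

setMethod("show", "SimConfig", function(object) {
  d <- dim(object@lifetimeMap)
  cat("SimConfig:", d[1], "x", d[2], "pixels, T =", object@acqWindow,
      "ns,", object@nBins, "bins, IRF", object@irfCentre, "+/-",
      object@irfSigma, "ns, Ap =", object@afterpulsing,
      ", repRate =", object@repRate, "MHz, seed =", object@seed, "\n")
})
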