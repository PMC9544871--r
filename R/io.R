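# Persistence: multi-page 16-bit TIFF stacks with plain-text sidecar
# metadata, 32-bit float lifetime maps with validity masks, and Gaussian-fit
# summaries of lifetime distributions.

.writeSidecar <- function(path, values) {
  lines <- vapply(names(values), function(k)
    paste0(k, ": ", paste(values[[k]], collapse = " ")), character(1))
  writeLines(lines, path)
}

.readSidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  out <- list()
  for (p in kv) {
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = ":"))
    tok <- strsplit(val, "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(tok))
    out[[key]] <- if (all(!is.na(num) | tok == "NA")) num else val
  }
  out
}

#' Write a FLIM stack as a multi-page 16-bit TIFF
#'
#' One TIFF page per time bin, in increasing time order; counts above 65535
#' raise an error naming the offending pixel (no silent clipping). A
#' plain-text sidecar (\code{<path>.meta}) records the acquisition window,
#' bin count, repetition rate, after-pulsing, seed, and the ground-truth
#' map files when present (written as scaled 32-bit float TIFFs).
#'
#' @param stack a \linkS4class{FLIMStack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeFLIMStack <- function(stack, path) {
  stopifnot(is(stack, "FLIMStack"))
  cube <- stack@cube
  if (any(cube > 65535)) {
    bad <- which(cube > 65535, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "count %d at bin %d, pixel (%d, %d) exceeds the 16-bit maximum",
      cube[bad[1], bad[2], bad[3]], bad[1], bad[2], bad[3]))
  }
  d <- dim(cube)
  pages <- lapply(seq_len(d[1]), function(k)
    matrix(cube[k, , ] / 65535, d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(acqWindow = stack@acqWindow, nBins = d[1],
               repRate = stack@repRate, afterpulsing = stack@afterpulsing,
               seed = stack@seed)
  if (!is.null(stack@lifetimeMap)) {
    lifePath <- paste0(tools::file_path_sans_ext(path), "_truth_tau.tif")
    .writeFloatTIFF(stack@lifetimeMap, lifePath, scale = stack@acqWindow)
    meta$lifetimeMapFile <- basename(lifePath)
    meta$lifetimeMapScale <- stack@acqWindow
  }
  if (!is.null(stack@photonMap)) {
    photPath <- paste0(tools::file_path_sans_ext(path), "_truth_n.tif")
    photScale <- max(1, max(stack@photonMap))
    .writeFloatTIFF(stack@photonMap, photPath, scale = photScale)
    meta$photonMapFile <- basename(photPath)
    meta$photonMapScale <- photScale
  }
  .writeSidecar(paste0(path, ".meta"), meta)
  invisible(path)
}

# 32-bit float TIFF; values stored divided by `scale` so they fall in [0, 1]
# (the float writer only preserves that range). Non-finite entries are
# stored as 0; the validity mask carries their location.
.writeFloatTIFF <- function(m, path, scale) {
  v <- m / scale
  v[!is.finite(v)] <- 0
  tiff::writeTIFF(v, path, bits.per.sample = 32)
  invisible(path)
}

.readFloatTIFF <- function(path, scale) {
  tiff::readTIFF(path) * scale
}

#' Read a FLIM stack from a multi-page TIFF
#'
#' Metadata come from the plain-text sidecar written by
#' \code{\link{writeFLIMStack}}; for foreign TIFFs without a sidecar the
#' acquisition window (and optionally repetition rate) must be given
#' explicitly.
#'
#' @param path TIFF path.
#' @param acqWindow acquisition window T in ns (overrides the sidecar).
#' @param repRate repetition rate in MHz (overrides the sidecar).
#' @return A \linkS4class{FLIMStack}.
#' @export
readFLIMStack <- function(path, acqWindow = NULL, repRate = NULL) {
  sidecar <- paste0(path, ".meta")
  meta <- if (file.exists(sidecar)) .readSidecar(sidecar) else list()
  if (is.null(acqWindow)) acqWindow <- meta$acqWindow
  if (is.null(repRate)) repRate <- if (!is.null(meta$repRate)) meta$repRate else 20
  if (is.null(acqWindow))
    stop("no sidecar found and no acquisition metadata given; ",
         "required keys: acqWindow (ns), optionally repRate (MHz)")
  pages <- tiff::readTIFF(path, all = TRUE)
  nb <- length(pages)
  cube <- array(0, dim = c(nb, nrow(pages[[1]]), ncol(pages[[1]])))
  for (k in seq_len(nb)) cube[k, , ] <- round(pages[[k]] * 65535)
  life <- phot <- NULL
  dir <- dirname(path)
  if (!is.null(meta$lifetimeMapFile)) {
    f <- file.path(dir, meta$lifetimeMapFile)
    if (file.exists(f)) life <- .readFloatTIFF(f, meta$lifetimeMapScale)
  }
  if (!is.null(meta$photonMapFile)) {
    f <- file.path(dir, meta$photonMapFile)
    if (file.exists(f)) phot <- .readFloatTIFF(f, meta$photonMapScale)
  }
  FLIMStack(cube, acqWindow = acqWindow, repRate = repRate,
            afterpulsing = if (!is.null(meta$afterpulsing))
              meta$afterpulsing else NA_real_,
            lifetimeMap = life, photonMap = phot,
            seed = if (!is.null(meta$seed)) meta$seed else NA_real_)
}

#' Write a lifetime map
#'
#' The lifetime image is stored as a 32-bit float TIFF (values divided by a
#' scale recorded in the sidecar), the validity mask as a second TIFF
#' (\code{<path>_mask.tif}), and the sidecar records scale, window and
#' method.
#'
#' @param map a \linkS4class{LifetimeMap}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeLifetimeMap <- function(map, path) {
  stopifnot(is(map, "LifetimeMap"))
  finite <- map@tau[is.finite(map@tau)]
  scale <- if (length(finite) && max(finite) > 0) 2 * max(finite) else 1
  .writeFloatTIFF(map@tau, path, scale = scale)
  maskPath <- paste0(tools::file_path_sans_ext(path), "_mask.tif")
  tiff::writeTIFF(map@valid + 0, maskPath, bits.per.sample = 8)
  .writeSidecar(paste0(path, ".meta"), list(
    scale = scale, window = map@window, method = map@method,
    maskFile = basename(maskPath)))
  invisible(path)
}

#' Read a lifetime map written by \code{\link{writeLifetimeMap}}
#'
#' @param path TIFF path (sidecar \code{<path>.meta} required).
#' @return A \linkS4class{LifetimeMap} (intensity is not stored; zeros).
#' @export
readLifetimeMap <- function(path) {
  meta <- .readSidecar(paste0(path, ".meta"))
  tau <- .readFloatTIFF(path, meta$scale)
  mask <- tiff::readTIFF(file.path(dirname(path), meta$maskFile)) > 0.5
  tau[!mask] <- NA_real_
  new("LifetimeMap", tau = tau, intensity = matrix(0, nrow(tau), ncol(tau)),
      valid = mask, window = meta$window, method = meta$method)
}

#' Write calibration parameters to a plain-text key/value file
#'
#' @param calibration a \linkS4class{CalibrationParams}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCalibration <- function(calibration, path) {
  stopifnot(is(calibration, "CalibrationParams"))
  prov <- calibration@provenance
  vals <- list(A = calibration@A, B = calibration@B, C = calibration@C,
               b = calibration@b, windows = calibration@windows,
               effWindows = calibration@effWindows,
               cutoffs = calibration@cutoffs, r2 = calibration@r2)
  for (k in c("seed", "nRepeats", "nPhotons", "afterpulsing"))
    if (!is.null(prov[[k]])) vals[[k]] <- prov[[k]]
  .writeSidecar(path, vals)
  invisible(path)
}

#' Read calibration parameters written by \code{\link{writeCalibration}}
#'
#' @param path file path.
#' @return A \linkS4class{CalibrationParams}.
#' @export
readCalibration <- function(path) {
  v <- .readSidecar(path)
  need <- c("A", "B", "C", "b", "windows", "effWindows", "cutoffs")
  if (!all(need %in% names(v)))
    stop("calibration file is missing keys: ",
         paste(setdiff(need, names(v)), collapse = ", "))
  .makeCalibration(A = v$A, B = v$B, C = v$C, b = v$b, windows = v$windows,
      effWindows = v$effWindows, cutoffs = v$cutoffs,
      r2 = if (!is.null(v$r2)) v$r2 else NA_real_,
      provenance = v[setdiff(names(v), c(need, "r2"))])
}

#' Summarize a lifetime distribution
#'
#' Mean and standard deviation of the per-pixel lifetimes estimated by
#' fitting a Gaussian to the lifetime histogram (Freedman-Diaconis bin
#' width), alongside the raw moments. An all-invalid map yields an empty
#' summary with a warning.
#'
#' @param map a \linkS4class{LifetimeMap} or numeric vector of lifetimes.
#' @return data.frame with \code{n}, \code{mean}, \code{sd} (raw moments)
#'   and \code{gaussMean}, \code{gaussSd} (Gaussian-fit estimates; fall
#'   back to the raw moments when the fit fails).
#' @export
summarizeLifetimeMap <- function(map) {
  tau <- if (is(map, "LifetimeMap")) map@tau[map@valid] else map
  tau <- tau[is.finite(tau)]
  if (length(tau) < 2L) {
    warning("no valid lifetimes to summarize")
    return(data.frame(n = length(tau), mean = NA_real_, sd = NA_real_,
                      gaussMean = NA_real_, gaussSd = NA_real_))
  }
  h <- graphics::hist(tau, breaks = "FD", plot = FALSE)
  gm <- mean(tau); gs <- stats::sd(tau)
  if (length(h$mids) >= 4L && gs > 0) {
    df <- data.frame(x = h$mids, y = h$counts)
    fit <- tryCatch(
      stats::nls(y ~ a * exp(-(x - m)^2 / (2 * s^2)), data = df,
                 start = list(a = max(h$counts), m = gm, s = gs)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      gm <- unname(cf["m"]); gs <- abs(unname(cf["s"]))
    }
  }
  data.frame(n = length(tau), mean = mean(tau), sd = stats::sd(tau),
             gaussMean = gm, gaussSd = gs)
}
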