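#' Number of frames
#' @param x a Movie, ShiftSeries or FluorescenceTrace.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Acquisition frame rate (Hz)
#' @param x a Movie or FluorescenceTrace.
#' @return numeric scalar, Hz.
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' Raw intensity array of a movie
#' @param x a Movie.
#' @return numeric 3-D array (time x rows x cols).
#' @export
setGeneric("movieData", function(x) standardGeneric("movieData"))

#' Per-frame values of a fluorescence trace
#' @param x a FluorescenceTrace.
#' @return numeric vector.
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' Pipeline stage tag of a trace
#' @param x a FluorescenceTrace.
#' @return character scalar.
#' @export
setGeneric("traceStage", function(x) standardGeneric("traceStage"))

#' ROI ids of an RoiSet
#' @param x an RoiSet.
#' @return character vector of ids.
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))

#' Pixel set of one ROI
#' @param x an RoiSet.
#' @param id ROI id.
#' @return integer n x 2 matrix of (row, col) pixels.
#' @export
setGeneric("roiPixels", function(x, id) standardGeneric("roiPixels"))

#' Neuropil pixel set of one ROI
#' @param x an RoiSet.
#' @param id ROI id.
#' @return integer n x 2 matrix of (row, col) pixels, or NULL.
#' @export
setGeneric("neuropilPixels", function(x, id) standardGeneric("neuropilPixels"))

#' Per-frame shift matrix
#' @param x a ShiftSeries.
#' @return integer n x 2 matrix with columns dy, dx.
#' @export
setGeneric("shiftMatrix", function(x) standardGeneric("shiftMatrix"))

setMethod("nFrames", "Movie", function(x) dim(x@data)[1L])
setMethod("nFrames", "ShiftSeries", function(x) nrow(x@shifts))
setMethod("nFrames", "FluorescenceTrace", function(x) length(x@values))

setMethod("frameRate", "Movie", function(x) x@frameRate)
setMethod("frameRate", "FluorescenceTrace", function(x) x@frameRate)

setMethod("movieData", "Movie", function(x) x@data)
setMethod("traceValues", "FluorescenceTrace", function(x) x@values)
setMethod("traceStage", "FluorescenceTrace", function(x) x@stage)

setMethod("roiIds", "RoiSet", function(x) names(x@rois))
setMethod("roiPixels", "RoiSet", function(x, id) x@rois[[id]])
setMethod("neuropilPixels", "RoiSet", function(x, id) x@neuropil[[id]])
setMethod("shiftMatrix", "ShiftSeries", function(x) x@shifts)

setMethod("show", "Movie", function(object) {
  d <- dim(object@data)
  cat(sprintf("Movie: %d frames of %d x %d px at %.6g Hz (%.1f s)\n",
              d[1L], d[2L], d[3L], object@frameRate, d[1L] / object@frameRate))
  if (!is.na(object@pixelSizeUm)) {
    cat(sprintf("  pixel size: %.4g um\n", object@pixelSizeUm))
  }
  invisible(NULL)
})

setMethod("show", "RoiSet", function(object) {
  np <- sum(!vapply(object@neuropil, is.null, logical(1)))
  cat(sprintf("RoiSet: %d ROIs in a %d x %d image (%d with neuropil masks)\n",
              length(object@rois), object@imageDim[1L], object@imageDim[2L], np))
  invisible(NULL)
})

setMethod("show", "ShiftSeries", function(object) {
  s <- object@shifts
  cat(sprintf("ShiftSeries: %d frames, |dy| <= %d, |dx| <= %d (reference: %s)\n",
              nrow(s), max(abs(s[, 1L])), max(abs(s[, 2L])), object@referenceSpec))
  invisible(NULL)
})

setMethod("show", "FluorescenceTrace", function(object) {
  cat(sprintf("FluorescenceTrace [%s] roi=%s: %d frames at %.6g Hz\n",
              object@stage, object@roiId, length(object@values), object@frameRate))
  invisible(NULL)
})

setMethod("show", "SynapseAnnotation", function(object) {
  cat(sprintf(
    "SynapseAnnotation %s: %d-vertex bouton, %d-point active zone, %d vesicles (%s)\n",
    object@synapseId, nrow(object@bouton), nrow(object@activeZone),
    nrow(object@vesicles), object@units))
  invisible(NULL)
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d cells, rate %.4g Hz, neuropil coeff %.3g, %d frames of shifts\n",
    length(object@eventTimes), object@trueRate, object@neuropilCoeff,
    nrow(object@appliedShifts)))
  invisible(NULL)
})
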