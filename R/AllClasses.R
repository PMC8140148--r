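#' @import methods
NULL

#' Movie: a time-lapse fluorescence stack
#'
#' Container for a raw or motion-corrected two-photon recording: a 3-D
#' intensity array ordered time x rows x cols, plus the acquisition frame
#' rate and (optionally) the pixel size.
#'
#' @slot data numeric 3-D array, \code{[frame, row, col]}, non-negative.
#' @slot frameRate acquisition rate in Hz (> 0).
#' @slot pixelSizeUm pixel size in micrometres, \code{NA_real_} if unknown.
#' @export
setClass("Movie",
  representation(data = "array", frameRate = "numeric", pixelSizeUm = "numeric"),
  prototype(pixelSizeUm = NA_real_)
)

setValidity("Movie", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3-D array (time x rows x cols)")
  if (dim(d)[1L] < 1L) return("movie must contain at least one frame")
  if (anyNA(d) || any(!is.finite(d))) return("movie data must be finite")
  if (any(d < 0)) return("movie data must be non-negative")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0) {
    return("frameRate must be a single positive number")
  }
  TRUE
})

#' Construct a Movie
#'
#' @param data numeric 3-D array, frames first.
#' @param frameRate frames per second.
#' @param pixelSizeUm optional pixel size in micrometres.
#' @return A \linkS4class{Movie}.
#' @examples
#' m <- Movie(array(0, c(5, 8, 8)), frameRate = 30)
#' nFrames(m)
#' @export
Movie <- function(data, frameRate, pixelSizeUm = NA_real_) {
  new("Movie", data = data, frameRate = as.numeric(frameRate),
      pixelSizeUm = as.numeric(pixelSizeUm))
}

#' RoiSet: labelled pixel sets per neuron with neuropil masks
#'
#' Each ROI is the pixel set covering one soma; each ROI may carry a
#' neuropil annulus used for contamination compensation. Pixel coordinates
#' are 1-based \code{(row, col)} integer matrices. The validity method
#' enforces the contract that a neuropil mask never overlaps *any* ROI.
#'
#' @slot rois named list of n x 2 integer matrices (columns row, col).
#' @slot neuropil named list of n x 2 integer matrices, possibly empty.
#' @slot imageDim integer length-2: image rows, cols.
#' @export
setClass("RoiSet",
  representation(rois = "list", neuropil = "list", imageDim = "integer")
)

setValidity("RoiSet", function(object) {
  if (length(object@imageDim) != 2L || any(object@imageDim < 1L)) {
    return("imageDim must be two positive integers")
  }
  if (length(object@rois) == 0L) return("at least one ROI is required")
  if (is.null(names(object@rois)) || anyDuplicated(names(object@rois))) {
    return("rois must be uniquely named")
  }
  nr <- object@imageDim[1L]; nc <- object@imageDim[2L]
  keyAll <- integer(0)
  for (id in names(object@rois)) {
    px <- object@rois[[id]]
    if (!is.matrix(px) || ncol(px) != 2L || nrow(px) == 0L) {
      return(sprintf("ROI '%s': pixels must be a non-empty n x 2 matrix", id))
    }
    if (any(px[, 1L] < 1L) || any(px[, 1L] > nr) ||
        any(px[, 2L] < 1L) || any(px[, 2L] > nc)) {
      return(sprintf("ROI '%s': pixels out of image bounds", id))
    }
    keyAll <- c(keyAll, (px[, 2L] - 1L) * nr + px[, 1L])
  }
  for (id in names(object@neuropil)) {
    px <- object@neuropil[[id]]
    if (is.null(px)) next
    key <- (px[, 2L] - 1L) * nr + px[, 1L]
    if (any(key %in% keyAll)) {
      return(sprintf("neuropil mask of ROI '%s' overlaps an ROI pixel set", id))
    }
  }
  TRUE
})

#' Construct an RoiSet
#'
#' @param rois named list of n x 2 integer matrices of (row, col) pixels.
#' @param imageDim integer vector (rows, cols).
#' @param neuropil optional named list of neuropil pixel matrices.
#' @return An \linkS4class{RoiSet}.
#' @export
RoiSet <- function(rois, imageDim, neuropil = list()) {
  rois <- lapply(rois, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "integer"; m
  })
  neuropil <- lapply(neuropil, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "integer"; m
  })
  new("RoiSet", rois = rois, neuropil = neuropil,
      imageDim = as.integer(imageDim))
}

#' ShiftSeries: per-frame rigid displacements
#'
#' Integer (dy, dx) translations, one per frame, as estimated against a
#' reference image. dy is positive downward (row direction), dx positive
#' rightward (column direction); 0-based frame indexing in the CSV
#' interface, 1-based rows in R.
#'
#' @slot shifts integer n x 2 matrix, columns \code{dy}, \code{dx}.
#' @slot referenceSpec free-text description of the reference image.
#' @slot degenerate logical per frame: TRUE where the frame had zero
#'   variance and the shift defaulted to (0,0).
#' @export
setClass("ShiftSeries",
  representation(shifts = "matrix", referenceSpec = "character",
                 degenerate = "logical")
)

setValidity("ShiftSeries", function(object) {
  s <- object@shifts
  if (!is.matrix(s) || ncol(s) != 2L) return("shifts must be an n x 2 matrix")
  if (nrow(s) < 1L) return("shifts must cover at least one frame")
  if (any(s != round(s))) return("shifts must be integer-valued")
  if (length(object@degenerate) != nrow(s)) {
    return("degenerate flags must match the number of frames")
  }
  TRUE
})

#' Construct a ShiftSeries
#'
#' @param shifts n x 2 matrix of integer (dy, dx) per frame.
#' @param referenceSpec description of the reference image.
#' @param degenerate logical vector flagging zero-variance frames.
#' @return A \linkS4class{ShiftSeries}.
#' @export
ShiftSeries <- function(shifts, referenceSpec = "unspecified",
                        degenerate = rep(FALSE, nrow(shifts))) {
  shifts <- as.matrix(shifts)
  storage.mode(shifts) <- "integer"
  colnames(shifts) <- c("dy", "dx")
  new("ShiftSeries", shifts = shifts, referenceSpec = referenceSpec,
      degenerate = degenerate)
}

#' FluorescenceTrace: one ROI's signal at a given pipeline stage
#'
#' Carries the per-frame values together with the frame rate, the ROI it
#' came from, and a stage tag recording where in the pipeline the trace
#' sits (\code{raw}, \code{neuropil}, \code{compensated}, \code{filtered}
#' or \code{dff}). dff-stage traces are dimensionless.
#'
#' @slot values numeric vector, one value per frame.
#' @slot frameRate Hz.
#' @slot roiId character id of the source ROI.
#' @slot stage one of raw, neuropil, compensated, filtered, dff.
#' @export
setClass("FluorescenceTrace",
  representation(values = "numeric", frameRate = "numeric",
                 roiId = "character", stage = "character")
)

.traceStages <- c("raw", "neuropil", "compensated", "filtered", "dff")

setValidity("FluorescenceTrace", function(object) {
  if (length(object@values) < 1L) return("trace must have at least one frame")
  if (anyNA(object@values) || any(!is.finite(object@values))) {
    return("trace values must be finite")
  }
  if (length(object@frameRate) != 1L || object@frameRate <= 0) {
    return("frameRate must be a single positive number")
  }
  if (!(object@stage %in% .traceStages)) {
    return(sprintf("stage must be one of: %s", paste(.traceStages, collapse = ", ")))
  }
  TRUE
})

#' Construct a FluorescenceTrace
#'
#' @param values numeric per-frame values.
#' @param frameRate Hz.
#' @param roiId ROI identifier.
#' @param stage pipeline stage tag.
#' @return A \linkS4class{FluorescenceTrace}.
#' @export
FluorescenceTrace <- function(values, frameRate, roiId = "roi",
                              stage = "raw") {
  new("FluorescenceTrace", values = as.numeric(values),
      frameRate = as.numeric(frameRate), roiId = roiId, stage = stage)
}

#' SynapseAnnotation: one synapse's EM morphometry primitives
#'
#' The manual annotation of a single synapse on an electron micrograph:
#' the bouton outline (simple polygon), the active zone (polyline along
#' the presynaptic membrane), vesicle centroids, mitochondrion counts on
#' both sides, and the asymmetric-PSD flag. All coordinates share one
#' unit, nanometres by convention for EM.
#'
#' @slot synapseId character id.
#' @slot bouton n x 2 numeric matrix of polygon vertices (x, y).
#' @slot activeZone m x 2 numeric matrix of polyline vertices, m >= 2.
#' @slot vesicles k x 2 numeric matrix of centroids (possibly 0 rows).
#' @slot mitoPre,mitoPost non-negative mitochondrion counts.
#' @slot psdAsymmetric logical: pronounced asymmetric postsynaptic density.
#' @slot units coordinate unit label, default "nm".
#' @export
setClass("SynapseAnnotation",
  representation(synapseId = "character", bouton = "matrix",
                 activeZone = "matrix", vesicles = "matrix",
                 mitoPre = "integer", mitoPost = "integer",
                 psdAsymmetric = "logical", units = "character")
)

setValidity("SynapseAnnotation", function(object) {
  b <- object@bouton
  if (!is.numeric(b) || ncol(b) != 2L || nrow(b) < 3L) {
    return("bouton must be a numeric polygon with >= 3 vertices")
  }
  if (any(!is.finite(b))) return("bouton vertices must be finite")
  if (!isSimplePolygon(b)) return("bouton polygon must be simple (non-self-intersecting)")
  az <- object@activeZone
  if (!is.numeric(az) || ncol(az) != 2L || nrow(az) < 2L) {
    return("activeZone must be a polyline with >= 2 vertices")
  }
  if (polylineLength(az) <= 0) return("activeZone must have positive length")
  if (nrow(object@vesicles) > 0L && any(!is.finite(object@vesicles))) {
    return("vesicle centroids must be finite")
  }
  if (object@mitoPre < 0L || object@mitoPost < 0L) {
    return("mitochondrion counts must be non-negative")
  }
  TRUE
})

#' Construct a SynapseAnnotation
#'
#' @param synapseId id string.
#' @param bouton polygon vertex matrix (x, y).
#' @param activeZone polyline vertex matrix.
#' @param vesicles centroid matrix, may have zero rows.
#' @param mitoPre,mitoPost mitochondrion counts.
#' @param psdAsymmetric logical PSD asymmetry flag.
#' @param units coordinate units, default "nm".
#' @return A \linkS4class{SynapseAnnotation}.
#' @export
SynapseAnnotation <- function(synapseId, bouton, activeZone,
                              vesicles = matrix(numeric(0), 0, 2),
                              mitoPre = 0L, mitoPost = 0L,
                              psdAsymmetric = FALSE, units = "nm") {
  vesicles <- as.matrix(vesicles)
  if (ncol(vesicles) != 2L) vesicles <- matrix(numeric(0), 0, 2)
  new("SynapseAnnotation", synapseId = as.character(synapseId),
      bouton = as.matrix(bouton), activeZone = as.matrix(activeZone),
      vesicles = vesicles, mitoPre = as.integer(mitoPre),
      mitoPost = as.integer(mitoPost), psdAsymmetric = psdAsymmetric,
      units = units)
}

#' GroundTruth: simulator bookkeeping for recovery tests
#'
#' Everything the synthetic-data generator knows and downstream stages are
#' asked to recover: per-cell event times and amplitudes, the true event
#' rate, the shared neuropil trace and contamination coefficient, and the
#' rigid shifts applied to each movie frame.
#'
#' @slot eventTimes list of numeric vectors, seconds, sorted per cell.
#' @slot eventAmps list of numeric vectors, dF/F units, same lengths.
#' @slot trueRate scalar Poisson event rate, Hz.
#' @slot neuropilTrace numeric per-frame neuropil fluorescence.
#' @slot neuropilCoeff contamination coefficient in [0, 1].
#' @slot appliedShifts integer n x 2 (dy, dx) per frame (0 x 2 if none).
#' @export
setClass("GroundTruth",
  representation(eventTimes = "list", eventAmps = "list", trueRate = "numeric",
                 neuropilTrace = "numeric", neuropilCoeff = "numeric",
                 appliedShifts = "matrix")
)

setValidity("GroundTruth", function(object) {
  if (length(object@eventTimes) != length(object@eventAmps)) {
    return("eventTimes and eventAmps must have one entry per cell")
  }
  for (i in seq_along(object@eventTimes)) {
    if (length(object@eventTimes[[i]]) != length(object@eventAmps[[i]])) {
      return(sprintf("cell %d: event times and amplitudes differ in length", i))
    }
    if (is.unsorted(object@eventTimes[[i]])) {
      return(sprintf("cell %d: event times must be sorted", i))
    }
  }
  if (!(object@neuropilCoeff >= 0 && object@neuropilCoeff <= 1)) {
    return("neuropilCoeff must lie in [0, 1]")
  }
  TRUE
})
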