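# ROI/neuropil signal extraction, neuropil compensation, low-pass
# filtering and dF/F computation.

#' Extract the mean-pixel trace of a pixel set
#'
#' Per-frame unweighted mean of all pixels in the set: the standard
#' somatic signal readout ("fluorescence signals of all pixels within a
#' selected ROI were averaged").
#'
#' @param movie a \linkS4class{Movie}.
#' @param pixels n x 2 integer matrix of (row, col) pixels.
#' @param roiId id recorded on the resulting trace.
#' @param stage stage tag for the result, default "raw".
#' @return A \linkS4class{FluorescenceTrace}.
#' @export
extractTrace <- function(movie, pixels, roiId = "roi", stage = "raw") {
  stopifnot(is(movie, "Movie"))
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) stop("pixel set is empty")
  d <- movieData(movie)
  nr <- dim(d)[2L]; nc <- dim(d)[3L]
  if (any(pixels[, 1L] < 1L) || any(pixels[, 1L] > nr) ||
      any(pixels[, 2L] < 1L) || any(pixels[, 2L] > nc)) {
    stop("pixel set contains out-of-bounds pixels")
  }
  # linear indices into each frame slice
  lin <- (pixels[, 2L] - 1L) * nr + pixels[, 1L]
  nF <- dim(d)[1L]
  flat <- matrix(d, nrow = nF)  # frames x (nr*nc), column-major frame layout
  vals <- rowMeans(flat[, lin, drop = FALSE])
  FluorescenceTrace(vals, frameRate(movie), roiId = roiId, stage = stage)
}

#' Build a neuropil annulus mask for one ROI
#'
#' Pixels whose Chebyshev (chessboard) distance to the ROI lies in
#' \code{(innerPx, outerPx]}, clipped to the image and with the pixels of
#' *every* ROI removed so somatic signal never leaks into the neuropil
#' estimate. The annulus leaves an \code{innerPx} guard ring around the
#' soma.
#'
#' @param roiset an \linkS4class{RoiSet}.
#' @param id ROI id.
#' @param innerPx inner guard radius, pixels (default 2).
#' @param outerPx outer radius, pixels (default 8); must exceed innerPx.
#' @return n x 2 integer matrix of (row, col) pixels.
#' @export
makeNeuropilMask <- function(roiset, id, innerPx = 2L, outerPx = 8L) {
  stopifnot(is(roiset, "RoiSet"))
  .assertScalar(innerPx, "innerPx", min = 1, integer = TRUE)
  .assertScalar(outerPx, "outerPx", min = innerPx + 1, integer = TRUE)
  nr <- roiset@imageDim[1L]; nc <- roiset@imageDim[2L]
  px <- roiPixels(roiset, id)
  if (is.null(px)) stop("unknown ROI id: ", id)
  seed <- matrix(FALSE, nr, nc)
  seed[px] <- TRUE
  outer <- .dilateChebyshev(seed, outerPx)
  inner <- .dilateChebyshev(seed, innerPx)
  band <- outer & !inner
  for (other in roiIds(roiset)) {
    band[roiPixels(roiset, other)] <- FALSE
  }
  hits <- which(band, arr.ind = TRUE)
  if (nrow(hits) == 0L) {
    stop(sprintf(
      "neuropil mask for ROI '%s' is empty; widen the annulus (inner %d, outer %d)",
      id, innerPx, outerPx))
  }
  colnames(hits) <- c("row", "col")
  hits
}

#' Attach neuropil masks to every ROI of a set
#'
#' @param roiset an \linkS4class{RoiSet}.
#' @param innerPx,outerPx annulus radii, see \code{\link{makeNeuropilMask}}.
#' @return The \linkS4class{RoiSet} with its \code{neuropil} slot filled.
#' @export
addNeuropilMasks <- function(roiset, innerPx = 2L, outerPx = 8L) {
  masks <- lapply(roiIds(roiset), function(id) {
    makeNeuropilMask(roiset, id, innerPx, outerPx)
  })
  names(masks) <- roiIds(roiset)
  roiset@neuropil <- masks
  validObject(roiset)
  roiset
}

# k-fold binary dilation with a 3x3 box kernel == Chebyshev distance <= k.
.dilateChebyshev <- function(mask, k) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (step in seq_len(k)) {
    m <- out
    up <- rbind(m[-1L, , drop = FALSE], m[nr, , drop = FALSE])
    down <- rbind(m[1L, , drop = FALSE], m[-nr, , drop = FALSE])
    grown <- m | up | down
    left <- cbind(grown[, -1L, drop = FALSE], grown[, nc, drop = FALSE])
    right <- cbind(grown[, 1L, drop = FALSE], grown[, -nc, drop = FALSE])
    out <- grown | left | right
  }
  out
}

#' Neuropil-compensated fluorescence
#'
#' The compensation rule
#' \deqn{F_{comp} = F_{ROI} - r \cdot F_{np} + r \cdot median(F_{np})}
#' with the median taken over the entire neuropil trace: the subtraction
#' removes the shared contamination while the median term restores the
#' trace's DC level so baselines stay positive. With constant neuropil the
#' trace passes through unchanged; with r = 0 compensation is the identity.
#'
#' @param fRoi raw ROI \linkS4class{FluorescenceTrace}.
#' @param fNeuropil neuropil \linkS4class{FluorescenceTrace} of equal
#'   length and frame rate.
#' @param r contamination coefficient in [0, 1], default 0.7.
#' @return A \linkS4class{FluorescenceTrace} tagged \code{compensated}.
#' @examples
#' fr <- FluorescenceTrace(c(10, 12), 30, "a", "raw")
#' fn <- FluorescenceTrace(c(2, 4), 30, "a", "neuropil")
#' traceValues(compensateNeuropil(fr, fn, 0.7))  # 10.7 11.3
#' @export
compensateNeuropil <- function(fRoi, fNeuropil, r = 0.7) {
  stopifnot(is(fRoi, "FluorescenceTrace"), is(fNeuropil, "FluorescenceTrace"))
  .assertScalar(r, "r", min = 0, max = 1)
  x <- traceValues(fRoi); np <- traceValues(fNeuropil)
  if (length(x) != length(np)) stop("trace lengths differ")
  if (frameRate(fRoi) != frameRate(fNeuropil)) stop("frame rates differ")
  vals <- x - r * np + r * stats::median(np)
  FluorescenceTrace(vals, frameRate(fRoi), roiId = fRoi@roiId,
                    stage = "compensated")
}

#' Zero-phase low-pass filter a trace
#'
#' 4th-order Butterworth applied forward and backward (zero phase, so
#' event onsets are not delayed), with reflection padding to avoid edge
#' transients; the cutoff defaults to the pipeline's 10 Hz. DC (the trace
#' mean) is preserved.
#'
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @param cutoffHz cutoff frequency, Hz; must be below Nyquist.
#' @param order filter order (default 4).
#' @return A \linkS4class{FluorescenceTrace} tagged \code{filtered}.
#' @export
lowpassTrace <- function(trace, cutoffHz = 10, order = 4L) {
  stopifnot(is(trace, "FluorescenceTrace"))
  vals <- .zeroPhaseLowpass(traceValues(trace), frameRate(trace), cutoffHz,
                            order)
  FluorescenceTrace(vals, frameRate(trace), roiId = trace@roiId,
                    stage = "filtered")
}

#' Compute dF/F with a rolling-percentile baseline
#'
#' Baseline F0(t) is the \code{baselinePercentile}-th percentile of the
#' trace over a centred window of \code{windowS} seconds (truncated at the
#' recording edges); dF/F = (F - F0) / F0. The low percentile makes the
#' baseline robust to event density.
#'
#' @param trace a positive-valued \linkS4class{FluorescenceTrace}.
#' @param baselinePercentile percentile in (0, 100), default 20.
#' @param windowS window length in seconds, default 30.
#' @return A dimensionless \linkS4class{FluorescenceTrace} tagged \code{dff}.
#' @export
computeDff <- function(trace, baselinePercentile = 20, windowS = 30) {
  stopifnot(is(trace, "FluorescenceTrace"))
  .assertScalar(baselinePercentile, "baselinePercentile", min = 0, max = 100,
                strictMin = TRUE, strictMax = TRUE)
  x <- traceValues(trace)
  fs <- frameRate(trace)
  w <- round(windowS * fs)
  if (w < 2) stop("windowS x frame rate must span at least 2 frames")
  f0 <- .rollingPercentile(x, w, baselinePercentile / 100)
  if (any(f0 <= 0)) {
    stop("baseline F0 is non-positive; dF/F undefined for this trace")
  }
  FluorescenceTrace((x - f0) / f0, fs, roiId = trace@roiId, stage = "dff")
}

# Rolling percentile with a centred window truncated at the edges.
# Exact (quantile type 7) at every position.
.rollingPercentile <- function(x, w, p) {
  n <- length(x)
  half <- w %/% 2
  out <- numeric(n)
  # windows repeat while fully interior: compute unique interior window once
  # per position; cost O(n * w log w) which is fine at pipeline scales.
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- stats::quantile(x[lo:hi], p, names = FALSE, type = 7)
  }
  out
}

#' Run the full trace pipeline for every ROI of a movie
#'
#' Extracts ROI and neuropil traces, compensates neuropil contamination,
#' low-pass filters, and computes dF/F, returning all stages in a long
#' data.frame (columns roi_id, frame, stage, value). Filtering is applied
#' after compensation.
#'
#' @param movie a registered \linkS4class{Movie}.
#' @param roiset an \linkS4class{RoiSet} with neuropil masks (masks are
#'   built on the fly when absent).
#' @param r contamination coefficient (default 0.7).
#' @param cutoffHz low-pass cutoff (default 10 Hz).
#' @param baselinePercentile,windowS dF/F baseline parameters.
#' @return List with \code{dff} (named list of dff-stage
#'   \linkS4class{FluorescenceTrace}s) and \code{table} (long data.frame
#'   of all stages).
#' @export
extractAllTraces <- function(movie, roiset, r = 0.7, cutoffHz = 10,
                             baselinePercentile = 20, windowS = 30) {
  stopifnot(is(movie, "Movie"), is(roiset, "RoiSet"))
  if (length(roiset@neuropil) == 0L) roiset <- addNeuropilMasks(roiset)
  dffs <- list()
  rows <- list()
  for (id in roiIds(roiset)) {
    fRoi <- extractTrace(movie, roiPixels(roiset, id), roiId = id)
    fNp <- extractTrace(movie, neuropilPixels(roiset, id), roiId = id,
                        stage = "neuropil")
    fComp <- compensateNeuropil(fRoi, fNp, r)
    fFilt <- lowpassTrace(fComp, cutoffHz)
    fDff <- computeDff(fFilt, baselinePercentile, windowS)
    dffs[[id]] <- fDff
    for (tr in list(fRoi, fNp, fComp, fFilt, fDff)) {
      rows[[length(rows) + 1L]] <- data.frame(
        roi_id = id, frame = seq_len(nFrames(tr)) - 1L,
        stage = traceStage(tr), value = traceValues(tr))
    }
  }
  list(dff = dffs, table = do.call(rbind, rows))
}
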