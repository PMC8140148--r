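# Calcium transient detection and per-cell / per-FOV activity metrics.

#' Detect calcium transients in a dF/F trace
#'
#' "Prominent" transients are operationalized as excursions above a robust
#' threshold: theta = median(dff) + kSigma * 1.4826 * MAD(dff). Events are
#' maximal runs of consecutive supra-threshold frames; runs separated by
#' at most \code{minGap} sub-threshold frames are bridged (so a
#' single-frame noise dip does not split one transient in two), and only
#' merged runs spanning at least \code{minRun} frames are kept — the
#' 20-frame criterion (~0.7 s at 30 Hz) in its printed frame units.
#' Amplitude is the maximum dF/F within the run.
#'
#' @param dff a dff-stage \linkS4class{FluorescenceTrace}.
#' @param kSigma threshold height in robust SDs (default 3).
#' @param minRun minimum run length in frames (default 20).
#' @param minGap largest sub-threshold gap bridged, frames (default 1).
#' @return data.frame with columns \code{onset_frame}, \code{offset_frame}
#'   (half-open, 0-based), \code{peak_frame}, \code{amplitude},
#'   \code{duration_frames}, sorted by onset; attribute \code{degenerate}
#'   is TRUE when MAD was zero (constant trace, no detection possible).
#' @examples
#' tr <- FluorescenceTrace(rnorm(1000), 30, stage = "dff")
#' detectTransients(tr)
#' @export
detectTransients <- function(dff, kSigma = 3, minRun = 20L, minGap = 1L) {
  stopifnot(is(dff, "FluorescenceTrace"))
  if (traceStage(dff) != "dff") stop("detectTransients expects a dff-stage trace")
  .assertScalar(kSigma, "kSigma", min = 0)
  .assertScalar(minRun, "minRun", min = 1, integer = TRUE)
  .assertScalar(minGap, "minGap", min = 0, integer = TRUE)
  x <- traceValues(dff)
  med <- stats::median(x)
  madSigma <- 1.4826 * stats::median(abs(x - med))
  empty <- data.frame(onset_frame = integer(0), offset_frame = integer(0),
                      peak_frame = integer(0), amplitude = numeric(0),
                      duration_frames = integer(0))
  if (madSigma == 0) {
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  theta <- med + kSigma * madSigma
  above <- x > theta
  if (!any(above)) {
    attr(empty, "degenerate") <- FALSE
    return(empty)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(start = starts[r$values], end = ends[r$values])
  # bridge gaps of <= minGap sub-threshold frames
  if (nrow(runs) > 1L && minGap > 0L) {
    merged <- runs[1L, , drop = FALSE]
    for (i in 2L:nrow(runs)) {
      gap <- runs[i, "start"] - merged[nrow(merged), "end"] - 1L
      if (gap <= minGap) {
        merged[nrow(merged), "end"] <- runs[i, "end"]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
    runs <- merged
  }
  span <- runs[, "end"] - runs[, "start"] + 1L
  runs <- runs[span >= minRun, , drop = FALSE]
  if (nrow(runs) == 0L) {
    attr(empty, "degenerate") <- FALSE
    return(empty)
  }
  events <- lapply(seq_len(nrow(runs)), function(i) {
    seg <- runs[i, "start"]:runs[i, "end"]
    pk <- seg[which.max(x[seg])]
    data.frame(onset_frame = runs[i, "start"] - 1L,
               offset_frame = runs[i, "end"],  # half-open [onset, offset)
               peak_frame = pk - 1L,
               amplitude = max(x[seg]),
               duration_frames = runs[i, "end"] - runs[i, "start"] + 1L)
  })
  out <- do.call(rbind, events)
  out <- out[order(out$onset_frame), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "degenerate") <- FALSE
  out
}

#' Classify a neuron as active
#'
#' A neuron is active when it shows at least one detected transient.
#'
#' @param events event table from \code{\link{detectTransients}}.
#' @return TRUE or FALSE.
#' @export
classifyActive <- function(events) {
  nrow(events) >= 1L
}

#' Per-cell activity metrics
#'
#' Transient frequency per minute and mean transient amplitude for one
#' cell; amplitude is NA when the cell has no events.
#'
#' @param events event table from \code{\link{detectTransients}}.
#' @param nFrames total frames in the recording.
#' @param frameRateHz acquisition rate, Hz.
#' @param roiId cell id carried through to the output.
#' @return One-row data.frame: roi_id, is_active, n_transients,
#'   frequency_per_min, mean_amplitude.
#' @examples
#' ev <- data.frame(onset_frame = 0, offset_frame = 30, peak_frame = 10,
#'                  amplitude = 0.5, duration_frames = 30)
#' cellMetrics(ev, nFrames = 15000, frameRateHz = 30)
#' @export
cellMetrics <- function(events, nFrames, frameRateHz, roiId = "roi") {
  .assertScalar(nFrames, "nFrames", min = 1, integer = TRUE)
  .assertScalar(frameRateHz, "frameRateHz", min = 0, strictMin = TRUE)
  minutes <- nFrames / frameRateHz / 60
  n <- nrow(events)
  data.frame(
    roi_id = roiId,
    is_active = n >= 1L,
    n_transients = n,
    frequency_per_min = n / minutes,
    mean_amplitude = if (n) mean(events$amplitude) else NA_real_)
}

#' Summarize activity over a field of view
#'
#' @param cells data.frame of per-cell rows from \code{\link{cellMetrics}}.
#' @return List: n_cells, n_active, fraction_active, and the pooled
#'   frequency and amplitude vectors (ordered by roi_id).
#' @export
summarizeFov <- function(cells) {
  if (!is.data.frame(cells) || nrow(cells) < 1L) {
    stop("at least one cell is required")
  }
  cells <- cells[order(cells$roi_id), , drop = FALSE]
  list(
    n_cells = nrow(cells),
    n_active = sum(cells$is_active),
    fraction_active = mean(cells$is_active),
    frequencies = cells$frequency_per_min,
    amplitudes = cells$mean_amplitude[!is.na(cells$mean_amplitude)])
}

#' Detect transients and summarize every cell of a FOV
#'
#' Applies \code{\link{detectTransients}} and \code{\link{cellMetrics}} to
#' each dff trace and assembles the per-cell table plus FOV summary.
#'
#' @param dffs named list of dff-stage traces (as from
#'   \code{\link{extractAllTraces}}).
#' @param kSigma,minRun,minGap detection parameters.
#' @return List with \code{events} (long data.frame with roi_id),
#'   \code{cells} (per-cell metrics) and \code{fov} (summary list).
#' @export
analyzeFov <- function(dffs, kSigma = 3, minRun = 20L, minGap = 1L) {
  evRows <- list()
  cellRows <- list()
  for (id in names(dffs)) {
    tr <- dffs[[id]]
    ev <- detectTransients(tr, kSigma, minRun, minGap)
    cellRows[[id]] <- cellMetrics(ev, nFrames(tr), frameRate(tr), roiId = id)
    if (nrow(ev)) evRows[[id]] <- cbind(roi_id = id, ev)
  }
  events <- if (length(evRows)) do.call(rbind, evRows) else
    data.frame(roi_id = character(0), onset_frame = integer(0),
               offset_frame = integer(0), peak_frame = integer(0),
               amplitude = numeric(0), duration_frames = integer(0))
  rownames(events) <- NULL
  cells <- do.call(rbind, cellRows)
  rownames(cells) <- NULL
  list(events = events, cells = cells, fov = summarizeFov(cells))
}
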