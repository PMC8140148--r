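# Render simulated traces into a movie with known rigid motion.

#' Simulate a two-photon movie with ROIs and known rigid motion
#'
#' Renders each cell as a disk carrying its (noise-free) somatic trace,
#' contaminated by a spatially uniform neuropil field scaled by the
#' contamination coefficient inside ROIs and unscaled elsewhere; applies
#' known integer per-frame (dy, dx) shifts with edge-replication padding,
#' then adds per-pixel Gaussian noise. Cells are laid out on a regular
#' grid with at least two disk radii between disk edges so ROIs never
#' overlap and neuropil annuli are well defined. The applied shifts are
#' recorded in the returned \linkS4class{GroundTruth} for registration
#' recovery tests.
#'
#' @param config a \code{\link{traceSimConfig}}.
#' @param imageDim integer (rows, cols) of each frame.
#' @param roiRadiusPx disk radius in pixels (default 3).
#' @param maxShiftPx maximum absolute applied shift, pixels (default 0).
#' @return List with \code{movie} (\linkS4class{Movie}), \code{rois}
#'   (\linkS4class{RoiSet} including neuropil annuli), \code{truth}
#'   (\linkS4class{GroundTruth} with applied shifts), and the trace
#'   simulation pieces (\code{signal}, \code{neuropil}).
#' @examples
#' cfg <- traceSimConfig(n_cells = 4, duration_s = 2, noise_sd = 0, seed = 1)
#' sim <- simulateMovie(cfg, imageDim = c(48, 48))
#' sim$movie
#' @export
simulateMovie <- function(config, imageDim = c(64L, 64L), roiRadiusPx = 3L,
                          maxShiftPx = 0L) {
  if (!inherits(config, "TraceSimConfig")) {
    stop("config must come from traceSimConfig()")
  }
  .assertScalar(roiRadiusPx, "roiRadiusPx", min = 1, integer = TRUE)
  .assertScalar(maxShiftPx, "maxShiftPx", min = 0, integer = TRUE)
  imageDim <- as.integer(imageDim)
  nr <- imageDim[1L]; nc <- imageDim[2L]

  centers <- .gridLayout(config$n_cells, nr, nc, roiRadiusPx, maxShiftPx)

  tr <- simulateTraces(config)
  nF <- config$n_frames

  # ROI pixel sets: disks around the grid centres
  rois <- vector("list", config$n_cells)
  names(rois) <- sprintf("roi%03d", seq_len(config$n_cells))
  roiMask <- matrix(0L, nr, nc)  # label image
  for (i in seq_len(config$n_cells)) {
    cy <- centers[i, 1L]; cx <- centers[i, 2L]
    ys <- max(1L, cy - roiRadiusPx):min(nr, cy + roiRadiusPx)
    xs <- max(1L, cx - roiRadiusPx):min(nc, cx + roiRadiusPx)
    grid <- expand.grid(row = ys, col = xs)
    keep <- (grid$row - cy)^2 + (grid$col - cx)^2 <= roiRadiusPx^2
    px <- as.matrix(grid[keep, , drop = FALSE])
    rois[[i]] <- px
    roiMask[px] <- i
  }

  shifts <- if (maxShiftPx > 0) {
    withSubstream(config$seed, "shifts", {
      cbind(dy = sample(-maxShiftPx:maxShiftPx, nF, replace = TRUE),
            dx = sample(-maxShiftPx:maxShiftPx, nF, replace = TRUE))
    })
  } else {
    cbind(dy = integer(nF), dx = integer(nF))
  }

  r <- config$neuropil_coeff
  data <- array(0, dim = c(nF, nr, nc))
  inRoi <- roiMask > 0L
  base <- matrix(0, nr, nc)
  for (f in seq_len(nF)) {
    frame <- base
    frame[!inRoi] <- tr$neuropil[f]
    for (i in seq_len(config$n_cells)) {
      frame[rois[[i]]] <- tr$signal[f, i] + r * tr$neuropil[f]
    }
    if (any(shifts[f, ] != 0L)) {
      frame <- .translateFrame(frame, shifts[f, 1L], shifts[f, 2L])
    }
    data[f, , ] <- frame
  }
  if (config$noise_sd > 0) {
    pixNoise <- withSubstream(config$seed, "noise", {
      array(stats::rnorm(length(data), 0, config$noise_sd), dim = dim(data))
    })
    data <- data + pixNoise
  }
  data <- pmax(data, 0)

  roiset <- RoiSet(rois, imageDim = imageDim)
  roiset <- addNeuropilMasks(roiset)

  truth <- tr$truth
  truth@appliedShifts <- matrix(as.integer(shifts), ncol = 2L,
                                dimnames = list(NULL, c("dy", "dx")))
  validObject(truth)

  list(movie = Movie(data, frameRate = config$frame_rate_hz),
       rois = roiset, truth = truth,
       signal = tr$signal, neuropil = tr$neuropil, config = config)
}

# Regular grid placement with >= 2 disk-radii edge spacing and a border
# margin wide enough for the applied shifts plus the default neuropil
# annulus. Errors if the requested cells cannot fit.
.gridLayout <- function(nCells, nr, nc, radius, maxShift) {
  margin <- radius + maxShift + 1L
  spacing <- 4L * radius + 2L  # centre distance: edges >= 2 radii apart
  ny <- max(1L, (nr - 2L * margin) %/% spacing + 1L)
  nx <- max(1L, (nc - 2L * margin) %/% spacing + 1L)
  if (ny * nx < nCells) {
    stop(sprintf(
      "image %d x %d cannot hold %d non-overlapping ROIs of radius %d (max %d)",
      nr, nc, nCells, radius, ny * nx))
  }
  ys <- margin + spacing * (seq_len(ny) - 1L) + radius
  xs <- margin + spacing * (seq_len(nx) - 1L) + radius
  grid <- as.matrix(expand.grid(row = ys, col = xs))
  grid[seq_len(nCells), , drop = FALSE]
}

# Integer translation with edge replication: content moves down by dy and
# right by dx; vacated borders repeat the nearest original pixel.
.translateFrame <- function(frame, dy, dx) {
  nr <- nrow(frame); nc <- ncol(frame)
  frame[.clampIndex(seq_len(nr) - dy, nr), .clampIndex(seq_len(nc) - dx, nc)]
}
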