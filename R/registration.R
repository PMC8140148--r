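# Rigid per-frame x/y translation correction, the first stage of the
# imaging pipeline. Integer shifts only; matching score is normalized
# cross-correlation on the overlap region (no circular wrap-around), which
# matches the edge-replication padding convention used when shifting.

#' Build a registration reference image
#'
#' Pixel-wise mean of the first \code{nRefFrames} frames.
#'
#' @param movie a \linkS4class{Movie}.
#' @param nRefFrames number of leading frames to average; must lie in
#'   1..nFrames (default 100).
#' @return A numeric matrix (rows x cols).
#' @export
buildReference <- function(movie, nRefFrames = 100L) {
  stopifnot(is(movie, "Movie"))
  nF <- nFrames(movie)
  .assertScalar(nRefFrames, "nRefFrames", min = 1, max = nF, integer = TRUE)
  d <- movieData(movie)
  ref <- apply(d[seq_len(nRefFrames), , , drop = FALSE], c(2L, 3L), mean)
  ref
}

#' Estimate per-frame rigid shifts against a reference
#'
#' For each frame, exhaustively scores every integer (dy, dx) candidate
#' within \code{+/-maxShift} by normalized cross-correlation between the
#' frame and the correspondingly displaced reference, restricted to their
#' overlap; the best-scoring shift wins. Ties are broken by smallest
#' |dy|+|dx|, then smallest dy, then smallest dx. A zero-variance frame
#' cannot be matched and is assigned shift (0,0) with a warning and a
#' degenerate flag.
#'
#' Convention: a returned shift (dy, dx) means the frame content sits dy
#' rows down and dx columns right of the reference; dy is positive
#' downward, 0-based frame indices in the CSV interface.
#'
#' @param movie a \linkS4class{Movie}.
#' @param reference matrix from \code{\link{buildReference}} (same shape
#'   as a frame).
#' @param maxShift maximum absolute shift searched, pixels (default 10).
#' @return A \linkS4class{ShiftSeries}.
#' @export
estimateShifts <- function(movie, reference, maxShift = 10L) {
  stopifnot(is(movie, "Movie"))
  .assertScalar(maxShift, "maxShift", min = 0, integer = TRUE)
  d <- movieData(movie)
  nr <- dim(d)[2L]; nc <- dim(d)[3L]
  if (!all(dim(reference) == c(nr, nc))) {
    stop("reference must have the same shape as a movie frame")
  }
  if (maxShift >= nr || maxShift >= nc) {
    stop("maxShift leaves no overlap between frame and reference")
  }
  cand <- expand.grid(dy = -maxShift:maxShift, dx = -maxShift:maxShift)
  # tie-break order: smallest |dy|+|dx|, then dy, then dx
  cand <- cand[order(abs(cand$dy) + abs(cand$dx), cand$dy, cand$dx), ]
  nF <- dim(d)[1L]
  shifts <- matrix(0L, nF, 2L)
  degenerate <- logical(nF)
  anyDegenerate <- FALSE
  for (f in seq_len(nF)) {
    frame <- d[f, , ]
    if (stats::var(as.vector(frame)) == 0) {
      degenerate[f] <- TRUE
      anyDegenerate <- TRUE
      next
    }
    best <- -Inf
    bestShift <- c(0L, 0L)
    for (k in seq_len(nrow(cand))) {
      dy <- cand$dy[k]; dx <- cand$dx[k]
      rowsF <- max(1L, 1L + dy):min(nr, nr + dy)
      colsF <- max(1L, 1L + dx):min(nc, nc + dx)
      a <- frame[rowsF, colsF]
      b <- reference[rowsF - dy, colsF - dx]
      va <- stats::var(as.vector(a)); vb <- stats::var(as.vector(b))
      score <- if (va == 0 || vb == 0) -Inf else
        stats::cor(as.vector(a), as.vector(b))
      if (score > best + 1e-12) {
        best <- score
        bestShift <- c(dy, dx)
      }
    }
    shifts[f, ] <- bestShift
  }
  if (anyDegenerate) {
    warning("constant (zero-variance) frame(s): shift set to (0,0)")
  }
  ShiftSeries(shifts,
              referenceSpec = sprintf("mean image; NCC search +/-%d px", maxShift),
              degenerate = degenerate)
}

#' Apply (undo) estimated shifts to a movie
#'
#' Translates each frame by the negated estimated shift, so that
#' estimating shifts on the result returns zeros. Vacated borders are
#' filled by edge replication.
#'
#' @param movie a \linkS4class{Movie}.
#' @param shifts a \linkS4class{ShiftSeries} of matching length.
#' @return A registered \linkS4class{Movie}.
#' @export
applyShifts <- function(movie, shifts) {
  stopifnot(is(movie, "Movie"), is(shifts, "ShiftSeries"))
  d <- movieData(movie)
  s <- shiftMatrix(shifts)
  if (nrow(s) != dim(d)[1L]) {
    stop("shift series length does not match the movie frame count")
  }
  for (f in seq_len(dim(d)[1L])) {
    if (any(s[f, ] != 0L)) {
      d[f, , ] <- .translateFrame(d[f, , ], -s[f, 1L], -s[f, 2L])
    }
  }
  Movie(d, frameRate = frameRate(movie), pixelSizeUm = movie@pixelSizeUm)
}

#' Register a movie (reference, estimate, apply)
#'
#' Convenience wrapper chaining \code{\link{buildReference}},
#' \code{\link{estimateShifts}} and \code{\link{applyShifts}}.
#'
#' @param movie a \linkS4class{Movie}.
#' @param maxShift search radius in pixels.
#' @param nRefFrames frames averaged into the reference.
#' @return List with \code{movie} (registered) and \code{shifts}.
#' @export
registerMovie <- function(movie, maxShift = 10L,
                          nRefFrames = min(100L, nFrames(movie))) {
  ref <- buildReference(movie, nRefFrames)
  sh <- estimateShifts(movie, ref, maxShift)
  list(movie = applyShifts(movie, sh), shifts = sh)
}

#' Write / read a shift series as CSV
#'
#' Columns \code{frame} (0-based), \code{dy}, \code{dx}.
#'
#' @param shifts a \linkS4class{ShiftSeries}.
#' @param path CSV file path.
#' @return \code{writeShiftsCsv}: the path, invisibly.
#' @export
writeShiftsCsv <- function(shifts, path) {
  s <- shiftMatrix(shifts)
  utils::write.csv(data.frame(frame = seq_len(nrow(s)) - 1L,
                              dy = s[, 1L], dx = s[, 2L]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeShiftsCsv
#' @return \code{readShiftsCsv}: a \linkS4class{ShiftSeries}.
#' @export
readShiftsCsv <- function(path) {
  df <- utils::read.csv(path)
  ShiftSeries(cbind(df$dy, df$dx), referenceSpec = sprintf("read from %s", path))
}
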