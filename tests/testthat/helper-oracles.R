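# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use brute-force formulations, not the package's
# code paths.

# Brute-force ECDF distance: max |Fa - Fb| over every pooled point.
oracleKsD <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(p) {
    abs(mean(a <= p) - mean(b <= p))
  }, numeric(1)))
}

# Shoelace-free polygon area by fan triangulation about a point the
# polygon is star-shaped around (the origin for randomStarPolygon
# fixtures): sum of unsigned triangle areas.
oracleFanArea <- function(poly, c0 = c(0, 0)) {
  n <- nrow(poly)
  s <- 0
  for (i in seq_len(n)) {
    p1 <- poly[i, ]; p2 <- poly[if (i == n) 1L else i + 1L, ]
    s <- s + abs((p1[1] - c0[1]) * (p2[2] - c0[2]) -
                   (p2[1] - c0[1]) * (p1[2] - c0[2])) / 2
  }
  s
}

# Dense-sampling point-to-polyline distance oracle.
oracleDenseDistance <- function(point, polyline, samplesPerSegment = 1e5) {
  best <- Inf
  for (i in seq_len(nrow(polyline) - 1L)) {
    t <- seq(0, 1, length.out = samplesPerSegment)
    sx <- polyline[i, 1] + t * (polyline[i + 1, 1] - polyline[i, 1])
    sy <- polyline[i, 2] + t * (polyline[i + 1, 2] - polyline[i, 2])
    best <- min(best, min((point[1] - sx)^2 + (point[2] - sy)^2))
  }
  sqrt(best)
}

# Exhaustive NCC shift search, written independently of estimateShifts.
oracleBestShift <- function(frame, reference, maxShift) {
  nr <- nrow(frame); nc <- ncol(frame)
  best <- -Inf; bestShift <- c(0L, 0L)
  grid <- expand.grid(dy = -maxShift:maxShift, dx = -maxShift:maxShift)
  grid <- grid[order(abs(grid$dy) + abs(grid$dx), grid$dy, grid$dx), ]
  for (k in seq_len(nrow(grid))) {
    dy <- grid$dy[k]; dx <- grid$dx[k]
    rf <- max(1, 1 + dy):min(nr, nr + dy)
    cf <- max(1, 1 + dx):min(nc, nc + dx)
    a <- as.vector(frame[rf, cf])
    b <- as.vector(reference[rf - dy, cf - dx])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    s <- stats::cor(a, b)
    if (s > best + 1e-12) { best <- s; bestShift <- c(dy, dx) }
  }
  bestShift
}

# Random star-convex simple polygon for geometry property tests.
randomStarPolygon <- function(nVerts = 10L, scale = 1) {
  # one vertex per angular slot, jittered within the slot: consecutive
  # angular gaps stay below pi, so the polygon is star-shaped about the
  # origin and the fan decomposition about the origin is exact
  slot <- 2 * pi / nVerts
  ang <- (seq_len(nVerts) - 1) * slot + stats::runif(nVerts, 0.05, 0.95) * slot
  r <- stats::runif(nVerts, 0.5, 1.5) * scale
  cbind(cos(ang) * r, sin(ang) * r)
}

# Build a movie whose frames are translations of one base image.
translatedMovie <- function(baseImage, shifts, frameRate = 30) {
  m <- Movie(array(rep(baseImage, each = nrow(shifts)),
                   dim = c(nrow(shifts), dim(baseImage))),
             frameRate = frameRate)
  # applyShifts translates by the negated shift, so negate to shift BY s
  applyShifts(m, ShiftSeries(-shifts))
}

# A dff-stage trace with bounded (uniform) noise plus rectangular
# supra-threshold pulses of given lengths at given onsets. Bounded noise
# keeps every non-pulse frame strictly below the robust threshold, so
# run-length boundary tests are deterministic.
pulseTrace <- function(n, onsets, lengths, height = 1, noiseSd = 0.01,
                       frameRate = 30) {
  x <- stats::runif(n, -noiseSd, noiseSd)
  for (i in seq_along(onsets)) {
    idx <- onsets[i]:(onsets[i] + lengths[i] - 1L)
    x[idx] <- height
  }
  FluorescenceTrace(x, frameRate, stage = "dff")
}
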