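# Planar geometry primitives for EM morphometry. All operate on n x 2
# numeric matrices of (x, y) coordinates in a single length unit.

#' Area of a simple polygon (shoelace formula)
#'
#' Absolute shoelace area of a simple (non-self-intersecting) polygon;
#' independent of vertex orientation. This is the measurement behind
#' manually outlined synaptic bouton areas on electron micrographs.
#'
#' @param polygon n x 2 numeric matrix of vertices, n >= 3. The polygon is
#'   closed implicitly (last vertex connects back to the first).
#' @return Area in squared coordinate units.
#' @examples
#' polygonArea(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
polygonArea <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
    stop("polygon must have >= 3 vertices in an n x 2 matrix")
  }
  if (any(!is.finite(polygon))) stop("polygon vertices must be finite")
  if (!isSimplePolygon(polygon)) {
    stop("polygon is self-intersecting or degenerate")
  }
  x <- polygon[, 1L]; y <- polygon[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Length of a polyline
#'
#' Sum of consecutive-vertex Euclidean distances; the active-zone length
#' measurement on EM annotations.
#'
#' @param polyline n x 2 numeric matrix of vertices, n >= 2.
#' @return Length in coordinate units.
#' @examples
#' polylineLength(rbind(c(0, 0), c(3, 4)))  # 5
#' @export
polylineLength <- function(polyline) {
  polyline <- as.matrix(polyline)
  if (ncol(polyline) != 2L || nrow(polyline) < 2L) {
    stop("polyline must have >= 2 vertices in an n x 2 matrix")
  }
  d <- diff(polyline)
  sum(sqrt(rowSums(d^2)))
}

#' Beeline distance from a point to a polyline
#'
#' Minimum Euclidean distance from a point to any segment of a polyline,
#' with the perpendicular foot clamped to segment endpoints. Used for the
#' vesicle-to-active-zone "beeline" distance.
#'
#' @param point length-2 numeric (x, y).
#' @param polyline n x 2 numeric matrix, n >= 2.
#' @return Non-negative distance in coordinate units.
#' @examples
#' pointPolylineDistance(c(5, 7), rbind(c(0, 0), c(10, 0)))  # 7
#' @export
pointPolylineDistance <- function(point, polyline) {
  polyline <- as.matrix(polyline)
  if (ncol(polyline) != 2L || nrow(polyline) < 2L) {
    stop("polyline must have >= 2 vertices")
  }
  a <- polyline[-nrow(polyline), , drop = FALSE]
  b <- polyline[-1L, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  ap <- cbind(point[1L] - a[, 1L], point[2L] - a[, 2L])
  t <- ifelse(len2 > 0, (ap[, 1L] * ab[, 1L] + ap[, 2L] * ab[, 2L]) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  fx <- a[, 1L] + t * ab[, 1L]
  fy <- a[, 2L] + t * ab[, 2L]
  sqrt(min((point[1L] - fx)^2 + (point[2L] - fy)^2))
}

# Proper / improper intersection test for two closed segments p1-p2, p3-p4,
# excluding shared endpoints (used for polygon simplicity).
.segmentsCross <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c) {
    v <- (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
    if (abs(v) < 1e-12 * max(1, abs(v))) 0 else sign(v)
  }
  onSeg <- function(a, b, c) {
    min(a[1L], b[1L]) - 1e-12 <= c[1L] && c[1L] <= max(a[1L], b[1L]) + 1e-12 &&
      min(a[2L], b[2L]) - 1e-12 <= c[2L] && c[2L] <= max(a[2L], b[2L]) + 1e-12
  }
  o1 <- orient(p1, p2, p3); o2 <- orient(p1, p2, p4)
  o3 <- orient(p3, p4, p1); o4 <- orient(p3, p4, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  if (o1 == 0 && onSeg(p1, p2, p3)) return(TRUE)
  if (o2 == 0 && onSeg(p1, p2, p4)) return(TRUE)
  if (o3 == 0 && onSeg(p3, p4, p1)) return(TRUE)
  if (o4 == 0 && onSeg(p3, p4, p2)) return(TRUE)
  FALSE
}

#' Test whether a polygon is simple
#'
#' A polygon is simple when no two non-adjacent edges intersect and
#' adjacent edges meet only at their shared vertex. O(n^2) pairwise test;
#' annotation polygons are small.
#'
#' @param polygon n x 2 numeric matrix of vertices.
#' @return TRUE or FALSE.
#' @export
isSimplePolygon <- function(polygon) {
  polygon <- as.matrix(polygon)
  n <- nrow(polygon)
  if (n < 3L) return(FALSE)
  if (anyDuplicated(polygon)) return(FALSE)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # adjacent edges (sharing a vertex) are allowed to touch there
      shared <- length(intersect(edges[i, ], edges[j, ])) > 0L
      if (shared) next
      if (.segmentsCross(polygon[edges[i, 1L], ], polygon[edges[i, 2L], ],
                         polygon[edges[j, 1L], ], polygon[edges[j, 2L], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Point-in-polygon test (even-odd rule)
#'
#' Ray-casting containment test for a set of points against a simple
#' polygon. Points exactly on an edge count as inside.
#'
#' @param points k x 2 numeric matrix (x, y).
#' @param polygon n x 2 numeric matrix of vertices.
#' @return Logical vector of length k.
#' @export
pointsInPolygon <- function(points, polygon) {
  points <- matrix(as.numeric(points), ncol = 2L)
  polygon <- as.matrix(polygon)
  n <- nrow(polygon)
  xs <- polygon[, 1L]; ys <- polygon[, 2L]
  xe <- c(xs[-1L], xs[1L]); ye <- c(ys[-1L], ys[1L])
  vapply(seq_len(nrow(points)), function(k) {
    px <- points[k, 1L]; py <- points[k, 2L]
    inside <- FALSE
    for (i in seq_len(n)) {
      x1 <- xs[i]; y1 <- ys[i]; x2 <- xe[i]; y2 <- ye[i]
      # boundary counts as inside
      d <- pointPolylineDistance(c(px, py), rbind(c(x1, y1), c(x2, y2)))
      if (d < 1e-12) return(TRUE)
      if ((y1 > py) != (y2 > py)) {
        xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (px < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}
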