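# EM synapse morphometry, puncta density, Cavalieri volumetry and the
# laminar density profile.

#' Bouton area
#'
#' Area of the manually outlined bouton polygon (absolute shoelace
#' formula); nm^2 for EM annotations.
#'
#' @param annotation a \linkS4class{SynapseAnnotation}, or a polygon
#'   vertex matrix.
#' @return Area in squared coordinate units.
#' @export
boutonArea <- function(annotation) {
  poly <- if (is(annotation, "SynapseAnnotation")) annotation@bouton else annotation
  polygonArea(poly)
}

#' Active-zone length
#'
#' Polyline length of the active-zone annotation; nm for EM.
#'
#' @param annotation a \linkS4class{SynapseAnnotation}, or a polyline
#'   vertex matrix.
#' @return Length in coordinate units.
#' @export
activeZoneLength <- function(annotation) {
  pl <- if (is(annotation, "SynapseAnnotation")) annotation@activeZone else annotation
  polylineLength(pl)
}

#' Vesicle-to-active-zone beeline distance
#'
#' Straight-line (minimum Euclidean) distance from a vesicle centroid to
#' the active-zone polyline, clamped to segment endpoints.
#'
#' @param vesicle length-2 numeric (x, y) centroid.
#' @param activeZone polyline vertex matrix, or a
#'   \linkS4class{SynapseAnnotation}.
#' @return Distance in coordinate units.
#' @export
vesicleAzDistance <- function(vesicle, activeZone) {
  pl <- if (is(activeZone, "SynapseAnnotation")) activeZone@activeZone else activeZone
  pointPolylineDistance(as.numeric(vesicle), pl)
}

#' Classify a synapse as inhibitory, excitatory, or unclassified
#'
#' Inhibitory synapses are identified by the presence of at least one
#' mitochondrion on each side of the synapse; otherwise, a pronounced
#' asymmetric postsynaptic density marks an excitatory synapse; anything
#' else is unclassified. The inhibitory rule takes precedence because it
#' is the explicit operational criterion; PSD asymmetry is secondary.
#'
#' @param annotation a \linkS4class{SynapseAnnotation}.
#' @return "inhibitory", "excitatory" or "unclassified".
#' @export
classifySynapse <- function(annotation) {
  stopifnot(is(annotation, "SynapseAnnotation"))
  if (annotation@mitoPre >= 1L && annotation@mitoPost >= 1L) return("inhibitory")
  if (annotation@psdAsymmetric) return("excitatory")
  "unclassified"
}

#' Morphometry table for a set of synapse annotations
#'
#' Computes, per synapse, class, bouton area, active-zone length and
#' vesicle count, plus one row per vesicle with its beeline distance to
#' the active zone. All annotations must share one coordinate unit;
#' mixing units is rejected.
#'
#' @param annotations list of \linkS4class{SynapseAnnotation}.
#' @return List with \code{synapses} (data.frame: synapse_id, class,
#'   area, az_length, vesicle_count, units) and \code{vesicles}
#'   (data.frame: synapse_id, vesicle, distance, units).
#' @export
synapseMetrics <- function(annotations) {
  if (!length(annotations)) {
    return(list(
      synapses = data.frame(synapse_id = character(0), class = character(0),
                            area = numeric(0), az_length = numeric(0),
                            vesicle_count = integer(0), units = character(0)),
      vesicles = data.frame(synapse_id = character(0), vesicle = integer(0),
                            distance = numeric(0), units = character(0))))
  }
  units <- unique(vapply(annotations, function(a) a@units, character(1)))
  if (length(units) != 1L) {
    stop("annotations mix coordinate units: ", paste(units, collapse = ", "))
  }
  synRows <- vector("list", length(annotations))
  vesRows <- list()
  for (i in seq_along(annotations)) {
    a <- annotations[[i]]
    area <- tryCatch(boutonArea(a), error = function(e) {
      stop(sprintf("synapse '%s': %s", a@synapseId, conditionMessage(e)),
           call. = FALSE)
    })
    synRows[[i]] <- data.frame(
      synapse_id = a@synapseId, class = classifySynapse(a),
      area = area, az_length = activeZoneLength(a),
      vesicle_count = nrow(a@vesicles), units = units)
    if (nrow(a@vesicles)) {
      d <- vapply(seq_len(nrow(a@vesicles)), function(v) {
        vesicleAzDistance(a@vesicles[v, ], a)
      }, numeric(1))
      vesRows[[length(vesRows) + 1L]] <- data.frame(
        synapse_id = a@synapseId, vesicle = seq_along(d), distance = d,
        units = units)
    }
  }
  list(
    synapses = do.call(rbind, synRows),
    vesicles = if (length(vesRows)) do.call(rbind, vesRows) else
      data.frame(synapse_id = character(0), vesicle = integer(0),
                 distance = numeric(0), units = character(0)))
}

#' Label 26-connected components of a binary 3-D stack
#'
#' @param stack logical 3-D array.
#' @param connectivity 26 (default) or 6.
#' @return Integer array of the same shape: 0 for background, 1..k
#'   component labels.
#' @export
labelComponents3d <- function(stack, connectivity = 26L) {
  if (!is.array(stack) || length(dim(stack)) != 3L) {
    stop("stack must be a 3-D array")
  }
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  dims <- dim(stack)
  fg <- which(stack != 0)
  labels <- array(0L, dim = dims)
  if (!length(fg)) return(labels)
  nodeOf <- integer(prod(dims))
  nodeOf[fg] <- seq_along(fg)
  coords <- arrayInd(fg, dims)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  # forward half of the neighbourhood is enough for an undirected graph
  keep <- (offs[, 1L] > 0) | (offs[, 1L] == 0 & offs[, 2L] > 0) |
    (offs[, 1L] == 0 & offs[, 2L] == 0 & offs[, 3L] > 0)
  offs <- offs[keep, , drop = FALSE]
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, offs[k, ], "+")
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
    if (!any(ok)) next
    lin <- (nb[ok, 3L] - 1L) * dims[1L] * dims[2L] +
      (nb[ok, 2L] - 1L) * dims[1L] + nb[ok, 1L]
    hit <- nodeOf[lin] > 0L
    if (!any(hit)) next
    edges[[length(edges) + 1L]] <- cbind(nodeOf[fg[ok]][hit], nodeOf[lin][hit])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)$membership
  labels[fg] <- as.integer(comp)
  labels
}

#' Puncta count and density with equivalent-diameter size filters
#'
#' Finds 26-connected components of a binary puncta stack, computes each
#' component's sphere-equivalent diameter d = (6V/pi)^(1/3) from its
#' voxel volume V, keeps components with minDiamUm <= d <= maxDiamUm
#' (the 0.01-1 um band by default), and reports the kept count divided by
#' the analysed volume. Optionally drops z slices from the top and bottom
#' of the stack before analysis, mirroring the practice of discarding the
#' outermost optical sections.
#'
#' @param stack logical 3-D array (z, y, x).
#' @param voxelSizeUm numeric (dz, dy, dx), um per voxel.
#' @param minDiamUm,maxDiamUm diameter band in um (defaults 0.01 and 1).
#' @param dropZSlices integer (top, bottom) slices removed (default c(0,0)).
#' @param connectivity component connectivity, default 26.
#' @return List: \code{count} (kept components), \code{density_per_um3},
#'   \code{volume_um3} (analysed volume), and \code{sizes} (data.frame:
#'   component, n_voxels, volume_um3, equiv_diameter_um, kept).
#' @export
punctaDensity <- function(stack, voxelSizeUm, minDiamUm = 0.01,
                          maxDiamUm = 1.0, dropZSlices = c(0L, 0L),
                          connectivity = 26L) {
  voxelSizeUm <- as.numeric(voxelSizeUm)
  if (length(voxelSizeUm) != 3L || any(voxelSizeUm <= 0)) {
    stop("voxelSizeUm must be three positive numbers")
  }
  dropZSlices <- as.integer(dropZSlices)
  nz <- dim(stack)[1L]
  zKeep <- (1L + dropZSlices[1L]):(nz - dropZSlices[2L])
  if (length(zKeep) < 1L || zKeep[1L] > zKeep[length(zKeep)]) {
    stop("dropZSlices leaves no analysed volume")
  }
  sub <- stack[zKeep, , , drop = FALSE]
  vol <- prod(dim(sub)) * prod(voxelSizeUm)
  labels <- labelComponents3d(sub, connectivity)
  k <- max(labels)
  voxVol <- prod(voxelSizeUm)
  if (k == 0L) {
    sizes <- data.frame(component = integer(0), n_voxels = integer(0),
                        volume_um3 = numeric(0), equiv_diameter_um = numeric(0),
                        kept = logical(0))
    return(list(count = 0L, density_per_um3 = 0, volume_um3 = vol,
                sizes = sizes))
  }
  counts <- tabulate(labels[labels > 0L], nbins = k)
  v <- counts * voxVol
  d <- (6 * v / pi)^(1 / 3)
  kept <- d >= minDiamUm & d <= maxDiamUm
  sizes <- data.frame(component = seq_len(k), n_voxels = counts,
                      volume_um3 = v, equiv_diameter_um = d, kept = kept)
  list(count = sum(kept), density_per_um3 = sum(kept) / vol,
       volume_um3 = vol, sizes = sizes)
}

#' Cavalieri volume estimate
#'
#' The stereological estimator: cumulative section area multiplied by the
#' slice increment, with no end correction.
#'
#' @param areas numeric per-slice areas, or a data.frame from
#'   \code{\link{simulateSliceAreas}} (column \code{area_mm2} with the
#'   increment attached as an attribute).
#' @param sliceIncrement slice spacing; required when \code{areas} is a
#'   plain numeric vector.
#' @return Volume in (area unit) x (increment unit), mm^3 for mm inputs.
#' @examples
#' cavalieriVolume(c(2, 3, 1), sliceIncrement = 0.5)  # 3
#' @export
cavalieriVolume <- function(areas, sliceIncrement = NULL) {
  if (is.data.frame(areas)) {
    if (is.null(sliceIncrement)) {
      sliceIncrement <- attr(areas, "slice_increment_mm")
    }
    areas <- areas$area_mm2
  }
  if (is.null(sliceIncrement)) stop("sliceIncrement is required")
  .assertScalar(sliceIncrement, "sliceIncrement", min = 0, strictMin = TRUE)
  if (any(areas < 0)) stop("slice areas must be non-negative")
  sum(areas) * sliceIncrement
}

#' Normalize a regional volume to intracranial volume
#'
#' @param regionVolume regional volume.
#' @param icvVolume intracranial volume (> 0), same units.
#' @return Percentage of ICV (100 x region / ICV).
#' @examples
#' normalizeToIcv(0.9852, 1)  # 98.52
#' @export
normalizeToIcv <- function(regionVolume, icvVolume) {
  .assertScalar(icvVolume, "icvVolume", min = 0, strictMin = TRUE)
  100 * regionVolume / icvVolume
}

#' Laminar density profile: object counts in equal-width bands
#'
#' Splits the ROI's extent along a direction into \code{nBins} equal-width
#' bands and counts the objects falling inside the ROI per band —
#' the 10-subregion depth profile used for neuronal density across
#' cortical layers. Band intervals are half-open [low, high) with the last
#' band closed, so every in-ROI object lands in exactly one band.
#'
#' @param centroids k x 2 numeric matrix of object centroids (x, y).
#' @param roiPolygon simple polygon vertex matrix.
#' @param nBins number of bands (default 10).
#' @param axis length-2 direction of the profile (default c(0, 1),
#'   i.e. the y axis); need not be normalized.
#' @return Integer vector of length \code{nBins}; sums to the number of
#'   centroids inside the ROI.
#' @export
laminarDensityProfile <- function(centroids, roiPolygon, nBins = 10L,
                                  axis = c(0, 1)) {
  .assertScalar(nBins, "nBins", min = 1, integer = TRUE)
  axis <- as.numeric(axis)
  nrmAx <- sqrt(sum(axis^2))
  if (nrmAx == 0) stop("axis must be a non-zero direction")
  axis <- axis / nrmAx
  roiPolygon <- as.matrix(roiPolygon)
  if (!isSimplePolygon(roiPolygon)) stop("ROI polygon must be simple")
  centroids <- matrix(as.numeric(centroids), ncol = 2L)
  projRoi <- roiPolygon %*% axis
  lo <- min(projRoi); hi <- max(projRoi)
  if (hi - lo <= 0) stop("ROI has degenerate extent along the axis")
  counts <- integer(nBins)
  if (nrow(centroids) == 0L) return(counts)
  inside <- pointsInPolygon(centroids, roiPolygon)
  if (!any(inside)) return(counts)
  proj <- centroids[inside, , drop = FALSE] %*% axis
  width <- (hi - lo) / nBins
  bin <- floor((proj - lo) / width) + 1L
  bin[bin > nBins] <- nBins  # closed last band
  bin[bin < 1L] <- 1L
  counts <- tabulate(bin, nbins = nBins)
  as.integer(counts)
}
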