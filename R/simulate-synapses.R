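# Synthetic EM synapse geometries with oracle-computed ground truth.

#' Configuration for synapse-geometry simulation
#'
#' Parameters of the synthetic EM annotation generator. Units are
#' nanometres (nm, nm^2), matching single-micrograph morphometry scales:
#' default bouton areas around 2.5e5 nm^2 (~0.25 um^2) and active zones
#' around 300 nm.
#'
#' @param n_synapses number of synapses (>= 0).
#' @param bouton_area_mean,bouton_area_sd bouton area distribution, nm^2.
#' @param az_length_mean,az_length_sd active-zone length distribution, nm.
#' @param vesicle_count_mean mean Poisson vesicle count per synapse (>= 0).
#' @param vesicle_spread_nm spatial spread of vesicles inside the bouton, nm.
#' @param class_mix fraction of inhibitory synapses in [0, 1].
#' @param seed master RNG seed.
#' @return Validated list of class \code{SynapseSimConfig}.
#' @export
synapseSimConfig <- function(n_synapses, bouton_area_mean = 2.5e5,
                             bouton_area_sd = 8e4, az_length_mean = 300,
                             az_length_sd = 80, vesicle_count_mean = 30,
                             vesicle_spread_nm = 200, class_mix = 0.5,
                             seed = 1L) {
  .assertScalar(n_synapses, "n_synapses", min = 0, integer = TRUE)
  .assertScalar(bouton_area_mean, "bouton_area_mean", min = 0)
  .assertScalar(bouton_area_sd, "bouton_area_sd", min = 0)
  .assertScalar(az_length_mean, "az_length_mean", min = 0)
  .assertScalar(az_length_sd, "az_length_sd", min = 0)
  .assertScalar(vesicle_count_mean, "vesicle_count_mean", min = 0)
  .assertScalar(vesicle_spread_nm, "vesicle_spread_nm", min = 0)
  .assertScalar(class_mix, "class_mix", min = 0, max = 1)
  .assertScalar(seed, "seed", integer = TRUE)
  structure(list(
    n_synapses = as.integer(n_synapses),
    bouton_area_mean = bouton_area_mean, bouton_area_sd = bouton_area_sd,
    az_length_mean = az_length_mean, az_length_sd = az_length_sd,
    vesicle_count_mean = vesicle_count_mean,
    vesicle_spread_nm = vesicle_spread_nm,
    class_mix = class_mix, seed = as.integer(seed)
  ), class = "SynapseSimConfig")
}

#' Simulate annotated synapses with ground-truth metrics
#'
#' Generates star-convex bouton polygons (radial perturbation around a
#' centre, guaranteeing simplicity), an active-zone polyline running along
#' a contiguous arc of the bouton boundary, Poisson-many vesicle centroids
#' inside the bouton, and class labels: inhibitory synapses get at least
#' one mitochondrion on each side, excitatory ones an asymmetric PSD.
#' Ground-truth area, active-zone length and per-vesicle beeline distances
#' are computed at generation time by independent oracles (fan
#' triangulation for area; dense per-segment sampling for distances) so
#' the morphometry engine can be checked against stored values.
#'
#' @param config a \code{\link{synapseSimConfig}}.
#' @param denseSamples oracle samples per active-zone segment (default 2000).
#' @return List with \code{annotations} (list of
#'   \linkS4class{SynapseAnnotation}) and \code{truth}, a list with
#'   per-synapse \code{area}, \code{azLength}, \code{vesicleDistances}
#'   (list of numeric vectors) and \code{class}.
#' @examples
#' sim <- simulateSynapses(synapseSimConfig(n_synapses = 3, seed = 2))
#' length(sim$annotations)
#' @export
simulateSynapses <- function(config, denseSamples = 2000L) {
  if (!inherits(config, "SynapseSimConfig")) {
    stop("config must come from synapseSimConfig()")
  }
  n <- config$n_synapses
  out <- vector("list", n)
  truthArea <- numeric(n)
  truthAz <- numeric(n)
  truthDist <- vector("list", n)
  classes <- character(n)
  if (n == 0L) {
    return(list(annotations = out,
                truth = list(area = truthArea, azLength = truthAz,
                             vesicleDistances = truthDist,
                             class = classes)))
  }
  withSubstream(config$seed, "synapses", {
    for (i in seq_len(n)) {
      poly <- .starPolygon(
        targetArea = max(stats::rnorm(1, config$bouton_area_mean,
                                      config$bouton_area_sd),
                         0.05 * config$bouton_area_mean),
        nVerts = sample(10:16, 1))
      # active zone: contiguous arc of the boundary whose chord length is
      # drawn from the configured distribution (clipped to the perimeter)
      azTarget <- max(stats::rnorm(1, config$az_length_mean,
                                   config$az_length_sd),
                      0.1 * max(config$az_length_mean, 1))
      az <- .boundaryArc(poly, azTarget)

      k <- stats::rpois(1, config$vesicle_count_mean)
      ves <- .sampleInsidePolygon(poly, k, config$vesicle_spread_nm)

      inhibitory <- stats::runif(1) < config$class_mix
      ann <- SynapseAnnotation(
        synapseId = sprintf("syn%04d", i), bouton = poly, activeZone = az,
        vesicles = ves,
        mitoPre = if (inhibitory) 1L + stats::rpois(1, 0.5) else 0L,
        mitoPost = if (inhibitory) 1L + stats::rpois(1, 0.5) else 0L,
        psdAsymmetric = !inhibitory, units = "nm")
      out[[i]] <- ann
      classes[i] <- if (inhibitory) "inhibitory" else "excitatory"
      truthArea[i] <- .fanTriangulationArea(poly)
      truthAz[i] <- sum(sqrt(rowSums(diff(az)^2)))
      truthDist[[i]] <- if (nrow(ves)) {
        vapply(seq_len(nrow(ves)), function(v) {
          .denseSampleDistance(ves[v, ], az, denseSamples)
        }, numeric(1))
      } else numeric(0)
    }
  })
  list(annotations = out,
       truth = list(area = truthArea, azLength = truthAz,
                    vesicleDistances = truthDist, class = classes))
}

# Star-shaped polygon with a given target area: one vertex per angular
# slot (jittered within the slot so gaps stay below pi and the shape is
# star-shaped about the origin), radial jitter, rescaled to the target.
.starPolygon <- function(targetArea, nVerts = 12L, center = c(0, 0)) {
  slot <- 2 * pi / nVerts
  ang <- (seq_len(nVerts) - 1L) * slot +
    stats::runif(nVerts, 0.05, 0.95) * slot
  rad <- stats::runif(nVerts, 0.6, 1.4)
  poly <- cbind(cos(ang) * rad, sin(ang) * rad)
  a0 <- .fanTriangulationArea(poly)
  s <- sqrt(targetArea / a0)
  sweep(poly * s, 2L, center, "+")
}

# Fan triangulation area oracle: sum of unsigned triangle areas about a
# point the polygon is star-shaped around (the generation centre).
.fanTriangulationArea <- function(poly, c0 = c(0, 0)) {
  n <- nrow(poly)
  total <- 0
  for (i in seq_len(n)) {
    p1 <- poly[i, ]; p2 <- poly[if (i == n) 1L else i + 1L, ]
    total <- total + abs((p1[1L] - c0[1L]) * (p2[2L] - c0[2L]) -
                           (p2[1L] - c0[1L]) * (p1[2L] - c0[2L])) / 2
  }
  total
}

# A contiguous boundary arc with approximately the requested length,
# starting at a random vertex and walking edges (with interpolation of the
# final point). Returns >= 2 points.
.boundaryArc <- function(poly, targetLen) {
  n <- nrow(poly)
  start <- sample.int(n, 1)
  pts <- poly[start, , drop = FALSE]
  acc <- 0
  i <- start
  repeat {
    j <- if (i == n) 1L else i + 1L
    seg <- poly[j, ] - poly[i, ]
    segLen <- sqrt(sum(seg^2))
    if (acc + segLen >= targetLen) {
      frac <- (targetLen - acc) / segLen
      frac <- max(frac, 1e-3)
      pts <- rbind(pts, poly[i, ] + frac * seg)
      break
    }
    acc <- acc + segLen
    pts <- rbind(pts, poly[j, ])
    i <- j
    if (i == start) break  # wrapped the full perimeter
  }
  pts
}

# Rejection-sample k points inside a polygon, biased toward the centroid
# with the given spread (truncated bivariate normal).
.sampleInsidePolygon <- function(poly, k, spread) {
  if (k == 0L) return(matrix(numeric(0), 0, 2))
  c0 <- colMeans(poly)
  out <- matrix(NA_real_, k, 2)
  got <- 0L
  tries <- 0L
  bbox <- apply(poly, 2L, range)
  while (got < k && tries < 10000L * k) {
    tries <- tries + 1L
    p <- if (spread > 0) c0 + stats::rnorm(2, 0, spread) else
      c(stats::runif(1, bbox[1, 1], bbox[2, 1]),
        stats::runif(1, bbox[1, 2], bbox[2, 2]))
    if (pointsInPolygon(matrix(p, 1), poly)) {
      got <- got + 1L
      out[got, ] <- p
    }
  }
  if (got < k) out <- out[seq_len(got), , drop = FALSE]
  out
}

# Dense-sampling distance oracle: minimum distance from a point to many
# uniformly spaced samples along each polyline segment.
.denseSampleDistance <- function(point, polyline, samplesPerSegment = 2000L) {
  best <- Inf
  for (i in seq_len(nrow(polyline) - 1L)) {
    t <- seq(0, 1, length.out = samplesPerSegment)
    sx <- polyline[i, 1L] + t * (polyline[i + 1L, 1L] - polyline[i, 1L])
    sy <- polyline[i, 2L] + t * (polyline[i + 1L, 2L] - polyline[i, 2L])
    best <- min(best, min((point[1L] - sx)^2 + (point[2L] - sy)^2))
  }
  sqrt(best)
}
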