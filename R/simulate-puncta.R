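# Binary puncta phantoms: voxelized spheres with known diameters.

#' Simulate a binary puncta stack with ground truth
#'
#' Voxelizes spheres of the requested diameters at random non-overlapping
#' centres (every pair of spheres keeps at least a two-voxel gap so
#' 26-connected components never merge). Ground truth records, per
#' sphere, the nominal diameter and the equivalent diameter implied by
#' its voxelized volume, which is what the downstream particle filter
#' sees.
#'
#' @param shape integer (z, y, x) stack dimensions.
#' @param voxelSizeUm numeric (dz, dy, dx) voxel edge lengths in um.
#' @param sphereDiametersUm numeric vector of sphere diameters in um
#'   (may be empty).
#' @param seed RNG seed.
#' @param maxTries placement retries per sphere before giving up.
#' @return List with \code{stack} (logical 3-D array, z first),
#'   \code{truth} (data.frame: sphere, diameter_um, equiv_diameter_um,
#'   n_voxels, cz, cy, cx) and \code{voxelSizeUm}.
#' @examples
#' ph <- simulatePunctaStack(c(20, 40, 40), c(0.1, 0.1, 0.1),
#'                           sphereDiametersUm = c(0.5, 0.5), seed = 1)
#' sum(ph$stack)
#' @export
simulatePunctaStack <- function(shape, voxelSizeUm, sphereDiametersUm,
                                seed = 1L, maxTries = 1000L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("shape must be three positive integers (z, y, x)")
  }
  voxelSizeUm <- as.numeric(voxelSizeUm)
  if (length(voxelSizeUm) != 3L || any(voxelSizeUm <= 0)) {
    stop("voxelSizeUm must be three positive numbers (dz, dy, dx)")
  }
  stack <- array(FALSE, dim = shape)
  nS <- length(sphereDiametersUm)
  truth <- data.frame(sphere = integer(0), diameter_um = numeric(0),
                      equiv_diameter_um = numeric(0), n_voxels = integer(0),
                      cz = numeric(0), cy = numeric(0), cx = numeric(0))
  if (nS == 0L) {
    return(list(stack = stack, truth = truth, voxelSizeUm = voxelSizeUm))
  }
  extent <- shape * voxelSizeUm  # physical size along (z, y, x)
  radii <- sphereDiametersUm / 2
  if (any(2 * radii > min(extent) - 2 * max(voxelSizeUm))) {
    stop("a sphere does not fit inside the stack")
  }
  gap <- 2 * max(voxelSizeUm)  # >= 2 voxels: keeps 26-components separate
  centers <- matrix(NA_real_, nS, 3)
  withSubstream(seed, "puncta", {
    for (i in seq_len(nS)) {
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        c_i <- vapply(1:3, function(d) {
          stats::runif(1, radii[i] + voxelSizeUm[d],
                       extent[d] - radii[i] - voxelSizeUm[d])
        }, numeric(1))
        ok <- TRUE
        if (i > 1L) {
          for (j in seq_len(i - 1L)) {
            if (sqrt(sum((c_i - centers[j, ])^2)) <=
                radii[i] + radii[j] + gap) { ok <- FALSE; break }
          }
        }
        if (ok) { centers[i, ] <- c_i; placed <- TRUE; break }
      }
      if (!placed) {
        stop(sprintf("could not place sphere %d without overlap after %d tries",
                     i, maxTries))
      }
    }
  })
  # voxel centre coordinates along each axis
  ax <- lapply(1:3, function(d) (seq_len(shape[d]) - 0.5) * voxelSizeUm[d])
  voxVol <- prod(voxelSizeUm)
  rows <- vector("list", nS)
  for (i in seq_len(nS)) {
    inz <- which(abs(ax[[1L]] - centers[i, 1L]) <= radii[i])
    iny <- which(abs(ax[[2L]] - centers[i, 2L]) <= radii[i])
    inx <- which(abs(ax[[3L]] - centers[i, 3L]) <= radii[i])
    count <- 0L
    for (z in inz) for (y in iny) {
      dz2 <- (ax[[1L]][z] - centers[i, 1L])^2
      dy2 <- (ax[[2L]][y] - centers[i, 2L])^2
      hit <- inx[(ax[[3L]][inx] - centers[i, 3L])^2 + dz2 + dy2 <= radii[i]^2]
      if (length(hit)) {
        stack[z, y, hit] <- TRUE
        count <- count + length(hit)
      }
    }
    if (count == 0L) {
      # tiny sphere below voxel resolution: keep its centre voxel
      zc <- which.min(abs(ax[[1L]] - centers[i, 1L]))
      yc <- which.min(abs(ax[[2L]] - centers[i, 2L]))
      xc <- which.min(abs(ax[[3L]] - centers[i, 3L]))
      stack[zc, yc, xc] <- TRUE
      count <- 1L
    }
    rows[[i]] <- data.frame(
      sphere = i, diameter_um = sphereDiametersUm[i],
      equiv_diameter_um = (6 * count * voxVol / pi)^(1 / 3),
      n_voxels = count,
      cz = centers[i, 1L], cy = centers[i, 2L], cx = centers[i, 3L])
  }
  list(stack = stack, truth = do.call(rbind, rows), voxelSizeUm = voxelSizeUm)
}
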