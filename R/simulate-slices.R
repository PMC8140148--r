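# Analytic slice-area phantoms for Cavalieri volumetry.

#' Analytic per-slice areas of a sphere or ellipsoid phantom
#'
#' Computes exact cross-section areas of a solid of revolution at slice
#' midplanes spaced by the slice increment, emulating the per-slice area
#' tables produced by manual MRI delineation. The Cavalieri estimator
#' (sum of areas times increment) applied to these tables converges to
#' the closed-form volume as the increment shrinks.
#'
#' @param solid "sphere" or "ellipsoid".
#' @param radii_mm radius (sphere) or three semi-axes (a, b, c) in mm;
#'   slicing runs along the last axis.
#' @param slice_increment_mm slice spacing in mm (> 0).
#' @return A data.frame with columns \code{slice_index} (1-based) and
#'   \code{area_mm2}, with the increment attached as attribute
#'   \code{slice_increment_mm}.
#' @examples
#' tab <- simulateSliceAreas("sphere", 1, 0.01)
#' cavalieriVolume(tab)  # ~ 4*pi/3
#' @export
simulateSliceAreas <- function(solid = c("sphere", "ellipsoid"), radii_mm,
                               slice_increment_mm) {
  solid <- match.arg(solid)
  .assertScalar(slice_increment_mm, "slice_increment_mm", min = 0,
                strictMin = TRUE)
  radii_mm <- as.numeric(radii_mm)
  if (any(radii_mm <= 0)) stop("radii must be positive")
  if (solid == "sphere") {
    if (length(radii_mm) != 1L) stop("a sphere takes a single radius")
    a <- b <- cc <- radii_mm
  } else {
    if (length(radii_mm) != 3L) stop("an ellipsoid takes three semi-axes")
    a <- radii_mm[1L]; b <- radii_mm[2L]; cc <- radii_mm[3L]
  }
  t <- slice_increment_mm
  nSlices <- ceiling(2 * cc / t)
  z <- -cc + (seq_len(nSlices) - 0.5) * t  # slice midplanes
  frac <- 1 - (z / cc)^2
  area <- pi * a * b * pmax(frac, 0)
  out <- data.frame(slice_index = seq_len(nSlices), area_mm2 = area)
  attr(out, "slice_increment_mm") <- t
  out
}
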