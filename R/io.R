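# File-format interfaces: multi-page TIFF movies, 16-bit label images,
# JSON annotations / ground truth, CSV tables.

#' Write / read a movie as multi-page TIFF
#'
#' Movies are stored the way acquisition software stores them: 16-bit
#' unsigned integer counts, one page per frame (intensities rounded to
#' the nearest count and clipped at 65535). The frame rate is not stored
#' by TIFF and must be supplied on read.
#'
#' @param movie a \linkS4class{Movie}.
#' @param path output TIFF path.
#' @return \code{writeMovieTiff}: the path, invisibly.
#' @export
writeMovieTiff <- function(movie, path) {
  d <- movieData(movie)
  pages <- lapply(seq_len(dim(d)[1L]), function(f) {
    pmin(round(d[f, , ]), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname writeMovieTiff
#' @param path TIFF path.
#' @param frameRate frame rate in Hz to attach on read.
#' @return \code{readMovieTiff}: a \linkS4class{Movie}.
#' @export
readMovieTiff <- function(path, frameRate) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nr <- nrow(pages[[1L]]); nc <- ncol(pages[[1L]])
  d <- array(0, dim = c(length(pages), nr, nc))
  for (f in seq_along(pages)) d[f, , ] <- round(pages[[f]] * 65535)
  Movie(d, frameRate = frameRate)
}

#' Write / read an ROI label image as 16-bit TIFF
#'
#' Label k maps to ROI id \code{roiNNN}; 0 is background. Neuropil masks
#' are not stored and are rebuilt from the annulus parameters on read.
#'
#' @param roiset an \linkS4class{RoiSet}.
#' @param path output TIFF path.
#' @return \code{writeRoiLabelsTiff}: the path, invisibly.
#' @export
writeRoiLabelsTiff <- function(roiset, path) {
  nr <- roiset@imageDim[1L]; nc <- roiset@imageDim[2L]
  lab <- matrix(0L, nr, nc)
  ids <- roiIds(roiset)
  for (k in seq_along(ids)) lab[roiPixels(roiset, ids[k])] <- k
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeRoiLabelsTiff
#' @param path TIFF path.
#' @return \code{readRoiLabelsTiff}: an \linkS4class{RoiSet} (without
#'   neuropil masks).
#' @export
readRoiLabelsTiff <- function(path) {
  img <- tiff::readTIFF(path)
  lab <- round(img * 65535)
  ks <- sort(unique(lab[lab > 0]))
  rois <- lapply(ks, function(k) {
    hits <- which(lab == k, arr.ind = TRUE)
    colnames(hits) <- c("row", "col")
    hits
  })
  names(rois) <- sprintf("roi%03d", as.integer(ks))
  RoiSet(rois, imageDim = dim(lab))
}

#' Write / read synapse annotations as JSON
#'
#' Versioned schema: an object with \code{schema_version} and a list of
#' synapses, each \code{\{synapse_id, bouton, active_zone, vesicles,
#' mito_pre, mito_post, psd_asymmetric, units\}} with coordinate arrays
#' as [[x, y], ...].
#'
#' @param annotations list of \linkS4class{SynapseAnnotation}.
#' @param path output JSON path.
#' @return \code{writeSynapseJson}: the path, invisibly.
#' @export
writeSynapseJson <- function(annotations, path) {
  payload <- list(
    schema_version = 1L,
    synapses = lapply(annotations, function(a) {
      list(synapse_id = a@synapseId,
           bouton = unname(apply(a@bouton, 1L, as.numeric, simplify = FALSE)),
           active_zone = unname(apply(a@activeZone, 1L, as.numeric,
                                      simplify = FALSE)),
           vesicles = if (nrow(a@vesicles))
             unname(apply(a@vesicles, 1L, as.numeric, simplify = FALSE))
           else list(),
           mito_pre = a@mitoPre, mito_post = a@mitoPost,
           psd_asymmetric = a@psdAsymmetric, units = a@units)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSynapseJson
#' @param path JSON path.
#' @return \code{readSynapseJson}: list of \linkS4class{SynapseAnnotation}.
#' @export
readSynapseJson <- function(path) {
  payload <- jsonlite::read_json(path)
  if (is.null(payload$schema_version) || payload$schema_version != 1L) {
    stop("unsupported synapse annotation schema version")
  }
  toMat <- function(lst) {
    if (!length(lst)) return(matrix(numeric(0), 0, 2))
    do.call(rbind, lapply(lst, function(p) c(p[[1L]], p[[2L]])))
  }
  lapply(payload$synapses, function(s) {
    SynapseAnnotation(
      synapseId = s$synapse_id, bouton = toMat(s$bouton),
      activeZone = toMat(s$active_zone), vesicles = toMat(s$vesicles),
      mitoPre = s$mito_pre, mitoPost = s$mito_post,
      psdAsymmetric = isTRUE(s$psd_asymmetric), units = s$units)
  })
}

#' Write / read a slice-area table as CSV
#'
#' Columns \code{slice_index}, \code{area_mm2}; the slice increment is
#' stored in a leading comment-free sidecar column \code{slice_increment_mm}
#' repeated per row so the file is self-contained.
#'
#' @param table data.frame from \code{\link{simulateSliceAreas}} (or with
#'   the same columns plus the increment attribute).
#' @param path output CSV path.
#' @return \code{writeSliceAreasCsv}: the path, invisibly.
#' @export
writeSliceAreasCsv <- function(table, path) {
  inc <- attr(table, "slice_increment_mm")
  if (is.null(inc)) stop("table lacks a slice_increment_mm attribute")
  utils::write.csv(data.frame(slice_index = table$slice_index,
                              area_mm2 = table$area_mm2,
                              slice_increment_mm = inc),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSliceAreasCsv
#' @param path CSV path.
#' @return \code{readSliceAreasCsv}: a data.frame with the increment
#'   attribute restored.
#' @export
readSliceAreasCsv <- function(path) {
  df <- utils::read.csv(path)
  out <- data.frame(slice_index = df$slice_index, area_mm2 = df$area_mm2)
  attr(out, "slice_increment_mm") <- df$slice_increment_mm[1L]
  out
}
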