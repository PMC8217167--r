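#' @include AllClasses.R
NULL

# Index registry. Each entry: the per-pixel formula over double-precision
# channel planes, the validity condition, and the fixed histogramming range.
# The ratio indices G/R and G/B are unbounded above; they are assigned the
# fixed range [0, 5] so histogram bins are comparable across samples
# (out-of-range pixels are clipped into the end bins at histogram time).
.indexRegistry <- list(
  GR   = list(range = c(0, 5),
              valid = function(R, G, B) R > 0,
              fun   = function(R, G, B) G / R),
  GB   = list(range = c(0, 5),
              valid = function(R, G, B) B > 0,
              fun   = function(R, G, B) G / B),
  NRI  = list(range = c(0, 1),
              valid = function(R, G, B) (R + G + B) > 0,
              fun   = function(R, G, B) R / (R + G + B)),
  NGI  = list(range = c(0, 1),
              valid = function(R, G, B) (R + G + B) > 0,
              fun   = function(R, G, B) G / (R + G + B)),
  NBI  = list(range = c(0, 1),
              valid = function(R, G, B) (R + G + B) > 0,
              fun   = function(R, G, B) B / (R + G + B)),
  GMRN = list(range = c(-1, 1),
              valid = function(R, G, B) (R + G + B) > 0,
              fun   = function(R, G, B) (G - R) / (R + G + B))
)

#' Compute one color-index raster
#'
#' Evaluates one of the six canopy color indices per pixel, on channel values
#' cast to double precision: \code{GR = G/R}, \code{GB = G/B},
#' \code{NRI = R/(R+G+B)}, \code{NGI = G/(R+G+B)}, \code{NBI = B/(R+G+B)} and
#' \code{GMRN = (G-R)/(R+G+B)}, the normalized green-minus-red index that
#' highlights vegetation. Pixels whose denominator is zero are masked invalid
#' (value \code{NA}) rather than clamped; the masked fraction is available
#' from the returned object's mask.
#'
#' @param image a \linkS4class{CanopyImage}.
#' @param indexName one of \code{"GR"}, \code{"GB"}, \code{"NRI"},
#'   \code{"NGI"}, \code{"NBI"}, \code{"GMRN"}.
#' @return An \linkS4class{IndexRaster}.
#' @examples
#' img <- CanopyImage(array(c(100, 150, 50), dim = c(1, 1, 3)))
#' indexValues(computeIndex(img, "GMRN"))  # (150-100)/300
#' @export
computeIndex <- function(image, indexName) {
  stopifnot(is(image, "CanopyImage"))
  if (!is.character(indexName) || length(indexName) != 1L ||
      !indexName %in% names(.indexRegistry))
    stopf("unknown color index '%s' (expected one of %s)",
          paste(indexName, collapse = ","),
          paste(names(.indexRegistry), collapse = ", "))
  reg <- .indexRegistry[[indexName]]
  px <- image@pixels
  R <- px[, , 1L] + 0; G <- px[, , 2L] + 0; B <- px[, , 3L] + 0
  if (is.null(dim(R))) { dim(R) <- dim(G) <- dim(B) <- dim(px)[1:2] }
  valid <- reg$valid(R, G, B)
  vals <- matrix(NA_real_, nrow(R), ncol(R))
  vals[valid] <- reg$fun(R, G, B)[valid]
  new("IndexRaster", values = vals, validMask = valid,
      indexName = indexName, theoreticalRange = reg$range)
}

#' Compute all six color-index rasters
#'
#' @param image a \linkS4class{CanopyImage}.
#' @return Named list of six \linkS4class{IndexRaster} objects, one per
#'   index, each identical to the corresponding \code{\link{computeIndex}}
#'   call.
#' @export
computeAllIndices <- function(image) {
  out <- lapply(names(.indexRegistry), function(nm) computeIndex(image, nm))
  names(out) <- names(.indexRegistry)
  out
}

#' Names of the supported color indices
#' @return Character vector of the six index names.
#' @export
colorIndexNames <- function() names(.indexRegistry)

#' Export an index raster as a single-band float TIFF
#'
#' For visual inspection in external viewers. Invalid pixels are written as
#' the lower range bound.
#'
#' @param raster an \linkS4class{IndexRaster}.
#' @param path output .tif path.
#' @return The path, invisibly.
#' @export
exportIndexTiff <- function(raster, path) {
  stopifnot(is(raster, "IndexRaster"))
  v <- raster@values
  v[!raster@validMask] <- raster@theoreticalRange[1]
  rng <- raster@theoreticalRange
  tiff::writeTIFF((v - rng[1]) / diff(rng), path, bits.per.sample = 32L)
  invisible(path)
}
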