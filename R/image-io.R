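#' @include AllClasses.R
NULL

.decodeRaster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  reader <- switch(ext,
    png = png::readPNG,
    jpg = , jpeg = jpeg::readJPEG,
    tif = , tiff = tiff::readTIFF,
    stopf("unsupported image format '%s' for '%s' (PNG/JPEG/TIFF expected)",
          ext, path)
  )
  tryCatch(reader(path),
           error = function(e) stopf("cannot decode image '%s': %s",
                                     path, conditionMessage(e)))
}

#' Read a canopy photograph
#'
#' Decodes a PNG, JPEG or TIFF file into a \linkS4class{CanopyImage}.
#' Grayscale sources are replicated across the three channels; an alpha
#' channel is dropped. Codecs return intensities on [0, 1] regardless of bit
#' depth, so 8-bit values round-trip exactly and 16-bit sources are linearly
#' rescaled onto 0-255.
#'
#' @param path image file.
#' @param sampleId sample identifier (defaults to the file name without
#'   extension).
#' @param cultivar,stage,nLevel optional metadata attached to the image.
#' @return A \linkS4class{CanopyImage}.
#' @export
readCanopyImage <- function(path, sampleId = NULL, cultivar = NA_character_,
                            stage = NA_character_, nLevel = NA_real_) {
  if (!file.exists(path)) stopf("image file not found: '%s'", path)
  arr <- .decodeRaster(path)
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  nch <- dim(arr)[3]
  if (nch == 1L) arr <- arr[, , c(1L, 1L, 1L), drop = FALSE]
  else if (nch == 2L) arr <- arr[, , c(1L, 1L, 1L), drop = FALSE]  # gray+alpha
  else if (nch >= 4L) arr <- arr[, , 1:3, drop = FALSE]
  else arr <- arr[, , 1:3, drop = FALSE]
  if (prod(dim(arr)[1:2]) < 1L) stopf("zero-size image: '%s'", path)
  px <- round(arr * 255)
  if (is.null(sampleId)) sampleId <- tools::file_path_sans_ext(basename(path))
  CanopyImage(px, sampleId = sampleId, cultivar = cultivar,
              stage = stage, nLevel = nLevel)
}

#' Write a canopy image as lossless 8-bit PNG
#'
#' @param image a \linkS4class{CanopyImage}.
#' @param path output file (.png).
#' @return The path, invisibly.
#' @export
writeCanopyImage <- function(image, path) {
  stopifnot(is(image, "CanopyImage"))
  png::writePNG(image@pixels / 255, target = path)
  invisible(path)
}

.SAMPLE_COLS <- c("sample_id", "image_path", "cultivar", "stage",
                  "n_level", "leaf_n", "yield")

#' Read a sample metadata table
#'
#' Parses the CSV linking each canopy photograph to its cultivar, growth
#' stage, nitrogen treatment and (optionally) measured leaf N content and
#' yield. Growth stage is parsed case-insensitively; samples lacking leaf N
#' or yield are kept and flagged as prediction-only via the added
#' \code{has_targets} column.
#'
#' @param path CSV file with header columns \code{sample_id}, \code{image_path},
#'   \code{cultivar}, \code{stage}, \code{n_level}, \code{leaf_n}, \code{yield}.
#' @return A data.frame, one row per sample in file order.
#' @export
readSampleTable <- function(path) {
  if (!file.exists(path)) stopf("sample table not found: '%s'", path)
  df <- readCsv(path)
  missing <- setdiff(.SAMPLE_COLS, names(df))
  if (length(missing))
    stopf("sample table '%s' lacks columns: %s", path,
          paste(missing, collapse = ", "))
  df <- df[, .SAMPLE_COLS]
  df$sample_id <- as.character(df$sample_id)
  # relative image paths are resolved against the table's own directory
  df$image_path <- as.character(df$image_path)
  rel <- !is.na(df$image_path) & nzchar(df$image_path) &
    !grepl("^(/|[A-Za-z]:)", df$image_path)
  df$image_path[rel] <- file.path(dirname(path), df$image_path[rel])
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stopf("duplicate sample_id in '%s': %s", path,
          paste(unique(dup), collapse = ", "))
  df$stage <- tolower(trimws(as.character(df$stage)))
  bad <- which(!df$stage %in% .STAGES)
  if (length(bad))
    stopf("unknown stage token in rows %s of '%s' (expected %s)",
          paste(bad, collapse = ", "), path, paste(.STAGES, collapse = "/"))
  for (col in c("n_level", "leaf_n", "yield"))
    df[[col]] <- as.numeric(df[[col]])
  if (any(df$leaf_n <= 0, na.rm = TRUE))
    stopf("leaf_n must be positive where present ('%s')", path)
  if (any(df$yield <= 0, na.rm = TRUE))
    stopf("yield must be positive where present ('%s')", path)
  df$has_targets <- !is.na(df$leaf_n) & !is.na(df$yield)
  df
}

#' Write a sample metadata table
#'
#' @param samples data.frame in the \code{\link{readSampleTable}} schema.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeSampleTable <- function(samples, path) {
  writeCsv(samples[, .SAMPLE_COLS], path)
}

#' Write a feature matrix to CSV
#'
#' Emits \code{sample_id}, the two target columns, then one column per
#' feature, at full double precision (read-back reproduces values to at
#' least 12 significant digits).
#'
#' @param features a \linkS4class{FeatureMatrix}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  stopifnot(is(features, "FeatureMatrix"))
  v <- featureValues(features)
  if (!all(is.finite(v))) stopf("feature matrix contains non-finite entries")
  df <- data.frame(sample_id = rownames(v),
                   leaf_n = features@targets$leaf_n,
                   yield = features@targets$yield,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(v, check.names = FALSE))
  writeCsv(df, path)
}

#' Read back a feature matrix written by \code{\link{writeFeatureTable}}
#'
#' @param path CSV path.
#' @param mode feature family of the stored matrix (\code{"IIMV"} or
#'   \code{"IIH"}).
#' @return A \linkS4class{FeatureMatrix}.
#' @export
readFeatureTable <- function(path, mode = c("IIMV", "IIH")) {
  mode <- match.arg(mode)
  df <- readCsv(path)
  featCols <- setdiff(names(df), c("sample_id", "leaf_n", "yield"))
  if (!length(featCols)) stopf("no feature columns in '%s'", path)
  v <- as.matrix(df[, featCols, drop = FALSE])
  rownames(v) <- as.character(df$sample_id)
  new("FeatureMatrix", values = v,
      targets = data.frame(leaf_n = df$leaf_n, yield = df$yield),
      mode = mode, recipe = list())
}
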