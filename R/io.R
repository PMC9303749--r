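#' Read a raster image as a panorama
#'
#' PNG is read natively; TIFF requires the `tiff` package. Intensities are
#' rescaled to 0-255; an alpha channel, if present, is dropped.
#'
#' @param path Image file path.
#' @param azimuth_origin Compass azimuth of column 1, degrees.
#' @return A [panorama()].
#' @export
read_panorama <- function(path, azimuth_origin = 0) {
  panorama(.read_raster(path) * 255, azimuth_origin = azimuth_origin)
}

.read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported raster format '%s' (use PNG or TIFF)", ext))
  )
  if (length(dim(px)) == 3L && dim(px)[3] == 4L)
    px <- px[, , 1:3, drop = FALSE]  # drop alpha
  if (length(dim(px)) == 3L && dim(px)[3] == 1L)
    px <- px[, , 1]
  px
}

#' Write a hemispherical image as PNG plus a JSON sidecar
#'
#' The sidecar (same path with `.json` appended) records the geometry
#' needed to reanalyze the raster: size, radius, lens function and azimuth
#' offset.
#'
#' @param img A `hemi_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_hemi <- function(img, path) {
  stopifnot(inherits(img, "hemi_image"))
  png::writePNG(img$pixels / 255, path)
  meta <- list(size = img$size, radius = img$radius,
               lens = unclass(img$lens), azimuth_offset = img$azimuth_offset)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a hemispherical image written by [write_hemi()]
#'
#' @param path PNG path with its `.json` sidecar alongside.
#' @return A `hemi_image`.
#' @export
read_hemi <- function(path) {
  px <- .read_raster(path) * 255
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lens <- lens_function(meta$lens$kind, meta$lens$coefficients,
                        meta$lens$theta_max)
  size <- meta$size
  g <- .hemi_polar(size)
  structure(list(pixels = px, size = size, radius = meta$radius, lens = lens,
                 azimuth_offset = meta$azimuth_offset,
                 outside_mask = g$r > meta$radius),
            class = "hemi_image")
}

#' Write a binary sky/plant mask as PNG plus a JSON summary
#'
#' @param mask A `binary_mask`.
#' @param path Output PNG path (white = sky, black = plant, gray = outside).
#' @param extra Named list merged into the JSON summary (e.g. the
#'   threshold provenance).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, extra = list()) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- matrix(0.5, nrow(mask$sky), ncol(mask$sky))
  inside <- !mask$outside_mask
  img[inside] <- as.numeric(mask$sky[inside])
  png::writePNG(img, path)
  info <- c(list(threshold = mask$threshold,
                 gap_fraction_overall = mean(mask$sky[inside])),
            extra)
  jsonlite::write_json(info, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
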