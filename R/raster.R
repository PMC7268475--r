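#' Multispectral raster container
#'
#' A minimal in-memory georeferenced raster holding the four Parrot-Sequoia
#' style bands (green, red, red-edge, near-infrared) in percent reflectance.
#' Coordinates are meters in a local planar CRS; any EPSG georeferencing is
#' carried as metadata only. Pixel (1,1) is the top-left pixel; the center of
#' pixel (i,j) is at `x = xmin + (j - 0.5) * gsd`, `y = ymax - (i - 0.5) * gsd`.
#'
#' @param bands numeric array `nrow x ncol x n_bands`, percent reflectance.
#' @param xmin,ymax coordinates of the top-left corner of the grid (meters).
#' @param gsd ground sample distance, meters per pixel.
#' @param band_names character vector naming the third dimension.
#' @param crs optional CRS tag (e.g. "EPSG:32616"), metadata only.
#'
#' @return An object of class `ms_raster`.
#' @export
ms_raster <- function(bands, xmin = 0, ymax = NULL, gsd = 0.0508,
                      band_names = c("G", "R", "RE", "NIR"), crs = NA_character_) {
  if (length(dim(bands)) == 2L) bands <- array(bands, c(dim(bands), 1L))
  stopifnot(length(dim(bands)) == 3L, gsd > 0)
  if (is.null(ymax)) ymax <- nrow(bands) * gsd
  if (length(band_names) != dim(bands)[3])
    stop("band_names length must match number of bands")
  dimnames(bands) <- list(NULL, NULL, band_names)
  structure(list(bands = bands, xmin = xmin, ymax = ymax, gsd = gsd, crs = crs),
            class = "ms_raster")
}

#' @export
print.ms_raster <- function(x, ...) {
  d <- dim(x$bands)
  cat(sprintf("<ms_raster> %d x %d px, %d band(s) [%s], gsd %.4f m\n",
              d[1], d[2], d[3], paste(dimnames(x$bands)[[3]], collapse = ","),
              x$gsd))
  cat(sprintf("  extent x [%.3f, %.3f], y [%.3f, %.3f] m\n",
              x$xmin, x$xmin + d[2] * x$gsd, x$ymax - d[1] * x$gsd, x$ymax))
  invisible(x)
}

#' @export
dim.ms_raster <- function(x) dim(x$bands)

#' Extract one band as a matrix
#' @param raster an [ms_raster].
#' @param band band name or index.
#' @return Numeric matrix (rows = image rows from the top).
#' @export
raster_band <- function(raster, band) {
  stopifnot(inherits(raster, "ms_raster"))
  raster$bands[, , band]
}

#' Pixel-center coordinates of a raster
#' @param raster an [ms_raster].
#' @return List with vectors `x` (per column) and `y` (per row, top to bottom).
#' @export
pixel_centers <- function(raster) {
  d <- dim(raster$bands)
  list(x = raster$xmin + (seq_len(d[2]) - 0.5) * raster$gsd,
       y = raster$ymax - (seq_len(d[1]) - 0.5) * raster$gsd)
}

#' Write / read a multispectral orthomosaic as TIFF + world file
#'
#' Bands are stored as 32-bit samples in G, R, RE, NIR order, scaled from
#' percent to fraction-of-unity reflectance on disk (the TIFF writer's value
#' range); the georeferencing goes to an ESRI world file (`.tfw`) next to
#' the TIFF so the output round-trips without a GDAL-style library.
#'
#' @param raster an [ms_raster].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_orthomosaic <- function(raster, path) {
  stopifnot(inherits(raster, "ms_raster"))
  if (max(raster$bands) > 100 || min(raster$bands) < 0)
    stop("reflectance must lie in [0, 100] percent to be written")
  tiff::writeTIFF(raster$bands / 100, path, bits.per.sample = 32L,
                  reduce = FALSE)
  wf <- sub("\\.tif{1,2}$", ".tfw", path, ignore.case = TRUE)
  if (identical(wf, path)) wf <- paste0(path, ".tfw")
  g <- raster$gsd
  writeLines(format(c(g, 0, 0, -g, raster$xmin + g / 2, raster$ymax - g / 2),
                    digits = 15), wf)
  invisible(path)
}

#' @rdname write_orthomosaic
#' @param band_names band names to assign on read.
#' @export
read_orthomosaic <- function(path, band_names = c("G", "R", "RE", "NIR")) {
  # a 4-band non-RGBA layout triggers a benign channel-interpretation note
  img <- withCallingHandlers(
    tiff::readTIFF(path, as.is = FALSE),
    warning = function(w) {
      if (grepl("ExtraSamples", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }) * 100
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  wf <- sub("\\.tif{1,2}$", ".tfw", path, ignore.case = TRUE)
  if (identical(wf, path)) wf <- paste0(path, ".tfw")
  if (file.exists(wf)) {
    w <- as.numeric(readLines(wf))
    gsd <- w[1]; xmin <- w[5] - gsd / 2; ymax <- w[6] + gsd / 2
  } else {
    gsd <- 1; xmin <- 0; ymax <- nrow(img)
  }
  ms_raster(img, xmin = xmin, ymax = ymax, gsd = gsd,
            band_names = band_names[seq_len(dim(img)[3])])
}
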