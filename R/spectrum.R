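#' Centroid mass spectrum
#'
#' Container for a centroided (peak-picked) mass spectrum: a list of
#' (m/z, intensity) peak apexes, optionally tagged with the pixel
#' coordinate it was acquired at and an instrument identifier.
#'
#' @param mz Numeric vector of m/z values in Da, strictly ascending.
#' @param intensity Numeric vector of non-negative intensities, same
#'   length as `mz`.
#' @param coord Optional integer pair `(row, col)`, 0-based.
#' @param instrument Optional instrument identifier string.
#'
#' @return An object of class `centroid_spectrum`.
#' @export
centroid_spectrum <- function(mz, intensity, coord = NULL, instrument = NULL) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length")
  }
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    stop("mz values must be strictly ascending")
  }
  if (any(intensity < 0)) {
    stop("intensities must be non-negative")
  }
  if (!is.null(coord)) {
    coord <- as.integer(coord)
    if (length(coord) != 2 || any(is.na(coord)) || any(coord < 0)) {
      stop("coord must be a non-negative integer pair (row, col)")
    }
  }
  structure(
    list(mz = mz, intensity = intensity, coord = coord,
         instrument = instrument),
    class = "centroid_spectrum"
  )
}

#' @export
print.centroid_spectrum <- function(x, ...) {
  cat(sprintf("<centroid_spectrum: %d peaks", length(x$mz)))
  if (length(x$mz)) {
    cat(sprintf(", m/z %.4f-%.4f", min(x$mz), max(x$mz)))
  }
  if (!is.null(x$coord)) cat(sprintf(", pixel (%d,%d)", x$coord[1], x$coord[2]))
  cat(">\n")
  invisible(x)
}

#' Mass spectrometry image
#'
#' A grid of per-pixel centroid spectra with a physical pixel size.
#' Pixels may be unmeasured (absent from `spectra`); coordinates are
#' 0-based `(row, col)`, row-major.
#'
#' @param spectra List of [centroid_spectrum] objects, each carrying a
#'   `coord` within the grid.
#' @param dims Integer pair `(rows, cols)` of the pixel grid.
#' @param pixel_um Pixel edge length in micrometers (> 0).
#' @param metadata Named list of free-form acquisition metadata.
#'
#' @return An object of class `spectrum_image`.
#' @export
spectrum_image <- function(spectra, dims, pixel_um, metadata = list()) {
  dims <- as.integer(dims)
  if (length(dims) != 2 || any(dims < 1)) stop("dims must be (rows, cols) >= 1")
  if (!is.numeric(pixel_um) || length(pixel_um) != 1 || pixel_um <= 0) {
    stop("pixel_um must be a positive scalar")
  }
  keys <- character(length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    if (!inherits(s, "centroid_spectrum")) {
      stop("all spectra must be centroid_spectrum objects")
    }
    if (is.null(s$coord)) stop("every spectrum in an image needs a coord")
    if (s$coord[1] >= dims[1] || s$coord[2] >= dims[2]) {
      stop(sprintf("coordinate (%d,%d) outside grid (%d,%d)",
                   s$coord[1], s$coord[2], dims[1], dims[2]))
    }
    keys[i] <- coord_key(s$coord[1], s$coord[2])
  }
  if (anyDuplicated(keys)) stop("duplicate pixel coordinates in image")
  names(spectra) <- keys
  structure(
    list(spectra = spectra, dims = dims, pixel_um = pixel_um,
         metadata = metadata),
    class = "spectrum_image"
  )
}

coord_key <- function(row, col) sprintf("%d,%d", row, col)

#' Number of measured pixels in an image
#' @param image A [spectrum_image].
#' @return Integer count of pixels carrying a spectrum.
#' @export
n_pixels <- function(image) {
  stopifnot(inherits(image, "spectrum_image"))
  length(image$spectra)
}

#' Retrieve the spectrum at a pixel
#' @param image A [spectrum_image].
#' @param row,col 0-based pixel coordinate.
#' @return The [centroid_spectrum] at that pixel, or `NULL` if unmeasured.
#' @export
pixel_spectrum <- function(image, row, col) {
  stopifnot(inherits(image, "spectrum_image"))
  image$spectra[[coord_key(row, col)]]
}

#' Coordinates of all measured pixels
#' @param image A [spectrum_image].
#' @return Data frame with integer columns `row`, `col` (0-based).
#' @export
measured_coords <- function(image) {
  stopifnot(inherits(image, "spectrum_image"))
  if (!length(image$spectra)) {
    return(data.frame(row = integer(0), col = integer(0)))
  }
  m <- t(vapply(image$spectra, function(s) s$coord, integer(2)))
  data.frame(row = m[, 1], col = m[, 2], row.names = NULL)
}

#' @export
print.spectrum_image <- function(x, ...) {
  cat(sprintf("<spectrum_image: %dx%d grid, %d measured pixels, %g um pixels>\n",
              x$dims[1], x$dims[2], length(x$spectra), x$pixel_um))
  invisible(x)
}
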