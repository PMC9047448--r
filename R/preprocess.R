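#' Mass binning grid
#'
#' Fixed-width, half-open mass bins `[lo + i*width, lo + (i+1)*width)`
#' anchored at `lo`. Defaults follow the recognition pipeline: m/z
#' 600-950 with 0.2 Da bins (1750 bins).
#'
#' @param lo,hi Mass range bounds in Da (`lo < hi`).
#' @param width Bin width in Da; `(hi - lo) / width` must be integral.
#' @return An object of class `bin_grid` with fields `lo`, `hi`, `width`,
#'   `n_bins`.
#' @export
bin_grid <- function(lo = 600, hi = 950, width = 0.2) {
  if (!(lo < hi)) stop("lo must be < hi")
  if (width <= 0) stop("width must be positive")
  n <- (hi - lo) / width
  if (abs(n - round(n)) > 1e-9) {
    stop("(hi - lo) / width must be an integer number of bins")
  }
  structure(list(lo = lo, hi = hi, width = width, n_bins = as.integer(round(n))),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid: m/z %g-%g, width %g, %d bins>\n",
              x$lo, x$hi, x$width, x$n_bins))
  invisible(x)
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(c(a$lo, a$hi, a$width), c(b$lo, b$hi, b$width),
                   tolerance = 1e-12))
}

#' Root-mean-square normalization
#'
#' Divides a centroid spectrum's intensities by their root mean square,
#' computed over the detected centroids, so that spectra are comparable
#' across pixels regardless of absolute signal. The output has rms 1;
#' m/z values are unchanged.
#'
#' @param spectrum A [centroid_spectrum] with at least one non-zero
#'   intensity.
#' @return The rms-normalized [centroid_spectrum].
#' @export
rms_normalize <- function(spectrum) {
  stopifnot(inherits(spectrum, "centroid_spectrum"))
  r <- sqrt(mean(spectrum$intensity^2))
  if (!is.finite(r) || r == 0) {
    stop("cannot rms-normalize an empty or all-zero spectrum")
  }
  spectrum$intensity <- spectrum$intensity / r
  spectrum
}

#' Bin a centroid spectrum onto a fixed grid
#'
#' Sums the intensity of every centroid with `lo <= mz < hi` into the
#' half-open bin `floor((mz - lo) / width)`; centroids outside the range
#' are dropped. Summing (rather than taking a maximum) conserves the
#' in-range ion count.
#'
#' @param spectrum A [centroid_spectrum].
#' @param grid A [bin_grid].
#' @return A `feature_vector`: list with `grid`, `values` (length
#'   `grid$n_bins`), and `provenance` carried over from the spectrum.
#' @export
bin_spectrum <- function(spectrum, grid = bin_grid()) {
  stopifnot(inherits(spectrum, "centroid_spectrum"),
            inherits(grid, "bin_grid"))
  values <- numeric(grid$n_bins)
  keep <- spectrum$mz >= grid$lo & spectrum$mz < grid$hi
  if (any(keep)) {
    mz <- spectrum$mz[keep]
    idx <- floor((mz - grid$lo) / grid$width)
    # guard against floating-point edge assignment at bin boundaries
    idx <- idx + (mz >= grid$lo + (idx + 1) * grid$width)
    idx <- idx - (mz < grid$lo + idx * grid$width)
    idx <- as.integer(idx) + 1L
    sums <- rowsum(spectrum$intensity[keep], idx)
    values[as.integer(rownames(sums))] <- sums[, 1]
  }
  structure(list(grid = grid, values = values,
                 provenance = list(coord = spectrum$coord)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector: %d bins, total %.4g>\n",
              length(x$values), sum(x$values)))
  invisible(x)
}

#' Mean spectrum of a region of interest
#'
#' The per-cell summary entering the spectral library: every ROI pixel's
#' spectrum is rms-normalized, binned onto `grid`, and the binned
#' vectors are averaged element-wise. The order is fixed as
#' normalize, then bin, then mean; the ROI mean is not re-normalized
#' afterwards. Pixels with all-zero spectra are excluded with a warning.
#'
#' @param image A [spectrum_image].
#' @param pixels Data frame with 0-based integer columns `row`, `col`.
#' @param grid A [bin_grid].
#' @return A `feature_vector` (the ROI mean).
#' @export
roi_mean_spectrum <- function(image, pixels, grid = bin_grid()) {
  stopifnot(inherits(image, "spectrum_image"))
  if (!nrow(pixels)) stop("ROI is empty")
  acc <- numeric(grid$n_bins)
  n_used <- 0L
  for (i in seq_len(nrow(pixels))) {
    s <- pixel_spectrum(image, pixels$row[i], pixels$col[i])
    if (is.null(s)) {
      stop(sprintf("ROI pixel (%d,%d) is not measured in the image",
                   pixels$row[i], pixels$col[i]))
    }
    if (!length(s$intensity) || all(s$intensity == 0)) {
      warning(sprintf("ROI pixel (%d,%d) has an all-zero spectrum; excluded",
                      pixels$row[i], pixels$col[i]))
      next
    }
    acc <- acc + bin_spectrum(rms_normalize(s), grid)$values
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("all ROI pixels had empty spectra")
  structure(list(grid = grid, values = acc / n_used,
                 provenance = list(n_pixels = n_used)),
            class = "feature_vector")
}
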