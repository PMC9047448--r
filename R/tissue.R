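#' Classify every pixel of a tissue image
#'
#' Applies a recognition model pixel by pixel: each measured pixel's
#' spectrum is rms-normalized, binned onto the model grid, and assigned
#' by nearest discriminant-space centroid ([classify()]). Unmeasured or
#' empty pixels become `"UNMEASURED"` and are excluded from the area
#' percentages (100% is the full measured region).
#'
#' @param model A `recognition_model`.
#' @param image A [spectrum_image].
#' @param mode `"outlier"` (unassignable pixels become `"OUTLIER"`) or
#'   `"force"` (every pixel gets the nearest class).
#' @return A `label_map`: list with `label` (character matrix),
#'   `pixel_um`, `percentages` (named, over measured pixels, summing to
#'   100), `n_measured`.
#' @export
classify_image <- function(model, image, mode = c("outlier", "force")) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "spectrum_image"))
  coords <- measured_coords(image)
  labels <- matrix("UNMEASURED", image$dims[1], image$dims[2])
  feats <- matrix(0, nrow = nrow(coords), ncol = model$grid$n_bins)
  usable <- logical(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    s <- image$spectra[[i]]
    if (length(s$intensity) && any(s$intensity > 0)) {
      feats[i, ] <- bin_spectrum(rms_normalize(s), model$grid)$values
      usable[i] <- TRUE
    }
  }
  if (!any(usable)) stop("image has no measured, non-empty pixels")
  pred <- classify_matrix(model, feats[usable, , drop = FALSE], mode)$label
  labels[cbind(coords$row[usable] + 1L, coords$col[usable] + 1L)] <- pred
  label_map(labels, image$pixel_um)
}

label_map <- function(labels, pixel_um) {
  measured <- labels[labels != "UNMEASURED"]
  pct <- if (length(measured)) {
    p <- 100 * table(measured) / length(measured)
    sort(stats::setNames(as.numeric(p), names(p)), decreasing = TRUE)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  structure(list(label = labels, pixel_um = pixel_um,
                 percentages = pct, n_measured = length(measured)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map: %dx%d, %d measured pixels>\n",
              nrow(x$label), ncol(x$label), x$n_measured))
  for (nm in names(x$percentages)) {
    cat(sprintf("  %-12s %6.2f%%\n", nm, x$percentages[nm]))
  }
  invisible(x)
}

#' Area percentages of a label map
#'
#' Label counts over measured pixels as percentages of the measured
#' region, in decreasing order. Percentages sum to 100.
#'
#' @param map A `label_map` from [classify_image()].
#' @return Data frame with columns `label`, `n_pixels`, `percent`.
#' @export
area_percentages <- function(map) {
  stopifnot(inherits(map, "label_map"))
  measured <- map$label[map$label != "UNMEASURED"]
  if (!length(measured)) stop("label map has no measured pixels")
  counts <- table(measured)
  df <- data.frame(label = names(counts),
                   n_pixels = as.integer(counts),
                   percent = 100 * as.integer(counts) / length(measured),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$percent, df$label), ]
  rownames(df) <- NULL
  df
}

#' Streaming per-spot classification
#'
#' Emulates on-the-fly recognition during an imaging run: spectra are
#' consumed one at a time, each classified independently and emitted
#' before the next is read, with per-spectrum latency recorded. Labels
#' are identical to batch [classify_image()] on the same spectra in the
#' same mode. Malformed records are logged as events with an `error`
#' message and the stream continues.
#'
#' @param model A `recognition_model`.
#' @param stream A list of [centroid_spectrum] objects (e.g. a replayed
#'   image's spectra), or a function that returns the next spectrum or
#'   `NULL` at end of stream.
#' @param mode `"outlier"` or `"force"`.
#' @return Data frame of events: `index`, `row`, `col`, `label`,
#'   `latency_s`, `error`; the mean latency is attached as attribute
#'   `mean_latency_s`.
#' @export
stream_classify <- function(model, stream, mode = c("outlier", "force")) {
  mode <- match.arg(mode)
  if (is.list(stream)) {
    items <- stream
    i <- 0L
    next_spectrum <- function() {
      i <<- i + 1L
      if (i > length(items)) NULL else items[[i]]
    }
  } else if (is.function(stream)) {
    next_spectrum <- stream
  } else {
    stop("stream must be a list of spectra or a generator function")
  }
  events <- list()
  idx <- 0L
  repeat {
    s <- next_spectrum()
    if (is.null(s)) break
    idx <- idx + 1L
    t0 <- proc.time()[["elapsed"]]
    ev <- tryCatch({
      if (!inherits(s, "centroid_spectrum")) stop("not a centroid spectrum")
      if (!length(s$intensity) || all(s$intensity == 0)) {
        stop("empty spectrum")
      }
      fv <- bin_spectrum(rms_normalize(s), model$grid)
      lab <- classify_matrix(model, matrix(fv$values, nrow = 1), mode)$label
      data.frame(index = idx,
                 row = if (is.null(s$coord)) NA_integer_ else s$coord[1],
                 col = if (is.null(s$coord)) NA_integer_ else s$coord[2],
                 label = lab, latency_s = NA_real_, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(index = idx, row = NA_integer_, col = NA_integer_,
                 label = NA_character_, latency_s = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    ev$latency_s <- proc.time()[["elapsed"]] - t0
    events[[idx]] <- ev
  }
  out <- if (length(events)) do.call(rbind, events) else {
    data.frame(index = integer(0), row = integer(0), col = integer(0),
               label = character(0), latency_s = numeric(0),
               error = character(0), stringsAsFactors = FALSE)
  }
  attr(out, "mean_latency_s") <- if (nrow(out)) mean(out$latency_s) else NA_real_
  out
}

#' Replay an image as a spectrum stream
#'
#' Flattens a [spectrum_image] into the row-major spectrum sequence a
#' streaming acquisition would produce, for feeding [stream_classify()].
#'
#' @param image A [spectrum_image].
#' @return List of [centroid_spectrum] objects in row-major pixel order.
#' @export
replay_image <- function(image) {
  stopifnot(inherits(image, "spectrum_image"))
  coords <- measured_coords(image)
  ord <- order(coords$row, coords$col)
  unname(image$spectra[ord])
}
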