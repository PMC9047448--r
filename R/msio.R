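#' Read an MSI image
#'
#' Reads a [spectrum_image] from processed-mode imzML or from the CSV
#' spectrum-table dialect (columns `row,col,mz,intensity`, 0-based
#' coordinates, one line per centroid).
#'
#' @param path Path to the `.imzML` or `.csv` file.
#' @param format `"imzml"` or `"csv"`; inferred from the extension when
#'   missing.
#' @param pixel_um Pixel size to attach when the file does not carry one.
#' @return A [spectrum_image].
#' @export
read_image <- function(path, format = c("auto", "imzml", "csv"),
                       pixel_um = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.imzml$", path, ignore.case = TRUE)) "imzml" else "csv"
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  switch(format,
         imzml = read_imzml(path, pixel_um = pixel_um),
         csv = read_image_csv(path, pixel_um = pixel_um))
}

#' Write an MSI image
#'
#' Inverse of [read_image()]; imzML is emitted in processed (centroided)
#' mode. Writers are atomic: output is staged in a temporary file in the
#' destination directory and renamed into place.
#'
#' @param image A [spectrum_image].
#' @param path Destination path.
#' @param format `"imzml"` or `"csv"`; inferred from the extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, format = c("auto", "imzml", "csv")) {
  stopifnot(inherits(image, "spectrum_image"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.imzml$", path, ignore.case = TRUE)) "imzml" else "csv"
  }
  switch(format,
         imzml = write_imzml(image, path),
         csv = write_image_csv(image, path))
  invisible(path)
}

# Stage-then-rename so readers never observe a half-written file.
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop(sprintf("cannot write to %s", path))
  invisible(path)
}

read_image_csv <- function(path, pixel_um = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("row", "col", "mz", "intensity")
  if (!all(need %in% names(df))) {
    stop(sprintf("malformed spectrum CSV %s: need columns %s", path,
                 paste(need, collapse = ",")))
  }
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad)) {
    stop(sprintf("malformed spectrum CSV %s: bad value at line %d", path,
                 bad[1] + 1L))  # +1 for header
  }
  if (is.null(pixel_um)) pixel_um <- 1
  if (!nrow(df)) {
    return(spectrum_image(list(), dims = c(1L, 1L), pixel_um = pixel_um))
  }
  key <- paste(df$row, df$col)
  spectra <- lapply(split(df, factor(key, levels = unique(key))), function(d) {
    ord <- order(d$mz)
    centroid_spectrum(d$mz[ord], d$intensity[ord],
                      coord = c(d$row[1], d$col[1]))
  })
  dims <- c(max(df$row) + 1L, max(df$col) + 1L)
  spectrum_image(unname(spectra), dims = dims, pixel_um = pixel_um)
}

write_image_csv <- function(image, path) {
  parts <- lapply(image$spectra, function(s) {
    if (!length(s$mz)) return(NULL)
    data.frame(row = s$coord[1], col = s$coord[2], mz = s$mz,
               intensity = s$intensity)
  })
  df <- do.call(rbind, c(parts, list(
    data.frame(row = integer(0), col = integer(0), mz = numeric(0),
               intensity = numeric(0)))))
  atomic_write(path, function(tmp) {
    utils::write.csv(format_num_df(df), tmp, row.names = FALSE, quote = FALSE)
  })
}

# full-precision decimal text for numeric columns (round-trip safe)
format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}

#' Read a table of cell ROIs
#'
#' Reads `cell_id,row,col,label` CSV rows into per-cell ROIs. Pixels are
#' grouped by cell id; a cell carrying two different labels is an error.
#' ROIs sharing a pixel are accepted here with a warning (the library
#' builder rejects them later).
#'
#' @param path CSV path.
#' @return List of `cell_roi` objects (`cell_id`, `pixels`, `label`).
#' @export
read_roi_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "row", "col", "label")
  if (!all(need %in% names(df))) {
    stop(sprintf("malformed ROI CSV %s: need columns %s", path,
                 paste(need, collapse = ",")))
  }
  rois <- lapply(split(df, factor(df$cell_id, levels = unique(df$cell_id))),
                 function(d) {
    if (length(unique(d$label)) > 1) {
      stop(sprintf("cell %s has conflicting labels: %s", d$cell_id[1],
                   paste(unique(d$label), collapse = ", ")))
    }
    cell_roi(cell_id = d$cell_id[1],
             pixels = data.frame(row = as.integer(d$row),
                                 col = as.integer(d$col)),
             label = d$label[1])
  })
  all_px <- paste(df$cell_id, df$row, df$col)
  shared <- paste(df$row, df$col)[duplicated(paste(df$row, df$col)) &
                                    !duplicated(all_px)]
  if (length(shared)) {
    warning(sprintf("%d pixel(s) shared between ROIs in %s",
                    length(unique(shared)), path))
  }
  unname(rois)
}

#' Write cell masks as a ROI table
#'
#' @param masks List of masks/ROIs with fields `cell_id`, `pixels`
#'   (`row`, `col`), `label` — e.g. `truth$cell_masks` from
#'   [synth_cell_image()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(masks, path) {
  parts <- lapply(masks, function(m) {
    data.frame(cell_id = m$cell_id, row = m$pixels$row, col = m$pixels$col,
               label = m$label)
  })
  df <- do.call(rbind, c(parts, list(
    data.frame(cell_id = character(0), row = integer(0), col = integer(0),
               label = character(0)))))
  atomic_write(path, function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  })
}

#' Write / read a per-pixel label matrix
#'
#' CSV dialect `row,col,label`, one line per labeled pixel, 0-based
#' coordinates.
#'
#' @param labels Character matrix of per-pixel labels (e.g.
#'   `truth$label` or `label_map$label`).
#' @param path CSV path.
#' @return `write_label_csv`: `path` invisibly; `read_label_csv`: a
#'   character matrix.
#' @export
write_label_csv <- function(labels, path) {
  idx <- which(!is.na(labels), arr.ind = TRUE)
  df <- data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                   label = labels[idx])
  df <- df[order(df$row, df$col), ]
  atomic_write(path, function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  })
}

#' @rdname write_label_csv
#' @export
read_label_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("row", "col", "label")
  if (!all(need %in% names(df))) {
    stop(sprintf("malformed label CSV %s: need columns %s", path,
                 paste(need, collapse = ",")))
  }
  m <- matrix(NA_character_, max(df$row) + 1L, max(df$col) + 1L)
  m[cbind(df$row + 1L, df$col + 1L)] <- df$label
  m
}
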