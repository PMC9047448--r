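#' Cell region of interest
#'
#' One cell's ROI: its pixel set and labels. Subtype and slide id are
#' optional at the I/O boundary but required for subtype-level models
#' and repeatability summaries.
#'
#' @param cell_id Unique cell identifier.
#' @param pixels Data frame with 0-based integer columns `row`, `col`;
#'   non-empty.
#' @param label Cell-line label (non-empty).
#' @param subtype Optional receptor subtype, one of [subtype_levels()].
#' @param slide_id Optional slide/measurement identifier.
#' @return An object of class `cell_roi`.
#' @export
cell_roi <- function(cell_id, pixels, label, subtype = NA_character_,
                     slide_id = NA_character_) {
  if (!nzchar(cell_id)) stop("cell_id must be non-empty")
  if (!nrow(pixels)) stop("ROI pixel set must be non-empty")
  if (!nzchar(label)) stop("label must be non-empty")
  if (!is.na(subtype) && !subtype %in% subtype_levels()) {
    stop(sprintf("unknown subtype %s", subtype))
  }
  structure(list(cell_id = cell_id,
                 pixels = data.frame(row = as.integer(pixels$row),
                                     col = as.integer(pixels$col)),
                 label = label, subtype = subtype, slide_id = slide_id),
            class = "cell_roi")
}

roi_overlaps <- function(rois) {
  keys <- unlist(lapply(rois, function(r) paste(r$pixels$row, r$pixels$col)))
  anyDuplicated(keys) > 0
}

#' Select the highest-intensity cells
#'
#' Ranks ROIs by total ion count (TIC: the sum of raw, pre-normalization
#' intensities over the ROI's pixels) and keeps the top ones, emulating
#' the selection of the brightest cells per slide for the library. Ties
#' are broken by lexicographic cell id. Overlapping ROIs are rejected:
#' a shared pixel would contribute evidence twice.
#'
#' @param image The [spectrum_image] the ROIs index into.
#' @param rois List of [cell_roi] objects.
#' @param keep How many to keep: a count (>= 1) or a fraction in (0, 1).
#' @return The selected ROIs, ranked by decreasing TIC.
#' @export
select_high_intensity_cells <- function(image, rois, keep = length(rois)) {
  if (roi_overlaps(rois)) {
    stop("ROIs overlap: each pixel may belong to at most one cell")
  }
  n <- if (keep < 1) max(1L, round(keep * length(rois))) else as.integer(keep)
  if (n > length(rois)) stop("keep exceeds the number of ROIs")
  tic <- vapply(rois, function(r) {
    total <- 0
    for (i in seq_len(nrow(r$pixels))) {
      s <- pixel_spectrum(image, r$pixels$row[i], r$pixels$col[i])
      if (is.null(s)) {
        stop(sprintf("ROI %s references unmeasured pixel (%d,%d)",
                     r$cell_id, r$pixels$row[i], r$pixels$col[i]))
      }
      total <- total + sum(s$intensity)
    }
    total
  }, numeric(1))
  ids <- vapply(rois, function(r) r$cell_id, character(1))
  ord <- order(-tic, ids)
  rois[ord][seq_len(n)]
}

#' Build a single-cell spectral library
#'
#' Turns images plus per-cell ROIs into the labeled training corpus: one
#' row per cell, the ROI mean spectrum ([roi_mean_spectrum()]:
#' rms-normalize, bin, average) with its cell-line label, subtype, slide
#' id and cell id.
#'
#' @param batches List of batches, each a list with elements `image` (a
#'   [spectrum_image]), `rois` (list of [cell_roi]), and optionally
#'   `slide_id` applied to ROIs lacking one.
#' @param grid The shared [bin_grid].
#' @return A `spectral_library`: list with `grid`, matrix `x` (cells x
#'   bins), data frame `meta` (`cell_id`, `label`, `subtype`,
#'   `slide_id`), and `classes`.
#' @export
build_library <- function(batches, grid = bin_grid()) {
  rows <- list()
  meta <- list()
  for (b in seq_along(batches)) {
    batch <- batches[[b]]
    for (r in batch$rois) {
      fv <- roi_mean_spectrum(batch$image, r$pixels, grid)
      rows[[length(rows) + 1L]] <- fv$values
      slide <- if (!is.na(r$slide_id)) r$slide_id
               else if (!is.null(batch$slide_id)) batch$slide_id
               else sprintf("batch%02d", b)
      meta[[length(meta) + 1L]] <- data.frame(
        cell_id = r$cell_id, label = r$label, subtype = r$subtype,
        slide_id = slide, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no ROIs supplied")
  x <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  classes <- sort(unique(meta$label))
  small <- names(which(table(meta$label) < 2))
  if (length(small)) {
    warning(sprintf("class(es) with fewer than 2 cells: %s (model fitting will refuse)",
                    paste(small, collapse = ", ")))
  }
  structure(list(grid = grid, x = x, meta = meta, classes = classes),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library: %d cells, %d classes, %d bins>\n",
              nrow(x$x), length(x$classes), ncol(x$x)))
  invisible(x)
}

#' Assemble a library directly from binned spectra
#'
#' Convenience constructor used by the synthetic pipeline and tests:
#' takes already rms-normalized, binned vectors instead of images.
#'
#' @param x Numeric matrix, cells x bins.
#' @param meta Data frame with columns `cell_id`, `label`, `subtype`,
#'   `slide_id` (missing ones are filled).
#' @param grid The [bin_grid] the columns of `x` follow.
#' @return A `spectral_library`.
#' @export
library_from_matrix <- function(x, meta, grid = bin_grid()) {
  if (ncol(x) != grid$n_bins) stop("x column count must match grid bins")
  if (nrow(x) != nrow(meta)) stop("x and meta row counts differ")
  for (nm in c("cell_id", "subtype", "slide_id")) {
    if (is.null(meta[[nm]])) meta[[nm]] <- NA_character_
  }
  if (is.null(meta$label)) stop("meta must carry a label column")
  structure(list(grid = grid, x = x,
                 meta = meta[c("cell_id", "label", "subtype", "slide_id")],
                 classes = sort(unique(meta$label))),
            class = "spectral_library")
}

#' Canonically sort a library
#'
#' Orders rows by (label, slide_id, cell_id) so that libraries built
#' from the same cells in different batch orders compare equal.
#'
#' @param library A `spectral_library`.
#' @return The sorted library.
#' @export
sort_library <- function(library) {
  ord <- order(library$meta$label, library$meta$slide_id,
               library$meta$cell_id)
  library$x <- library$x[ord, , drop = FALSE]
  library$meta <- library$meta[ord, , drop = FALSE]
  rownames(library$meta) <- NULL
  library
}

#' Within- and across-slide repeatability
#'
#' For every class, the mean pairwise cosine similarity of library rows
#' measured on the same slide and on different slides — a summary of
#' how repeatable the per-cell profiles are across cultures and days.
#'
#' @param library A `spectral_library` with slide ids.
#' @return Data frame with columns `label`, `within_slide`,
#'   `across_slide` (NA when the class was measured on a single slide),
#'   `n_cells`, `n_slides`.
#' @export
repeatability_report <- function(library) {
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  out <- lapply(library$classes, function(cl) {
    idx <- which(library$meta$label == cl)
    slides <- library$meta$slide_id[idx]
    within <- c(); across <- c()
    if (length(idx) > 1) {
      for (i in seq_along(idx)[-length(idx)]) {
        for (j in seq((i + 1), length(idx))) {
          s <- cosine(library$x[idx[i], ], library$x[idx[j], ])
          if (identical(slides[i], slides[j])) within <- c(within, s)
          else across <- c(across, s)
        }
      }
    }
    data.frame(label = cl,
               within_slide = if (length(within)) mean(within) else NA_real_,
               across_slide = if (length(across)) mean(across) else NA_real_,
               n_cells = length(idx),
               n_slides = length(unique(slides)))
  })
  do.call(rbind, out)
}

#' Relabel a library at the receptor-subtype level
#'
#' Replaces each row's cell-line label by its receptor subtype, the
#' roll-up used for the 3-class (triple negative / HER2+ / ER+PR+)
#' recognition model.
#'
#' @param library A `spectral_library` whose `meta$subtype` is filled.
#' @return A `spectral_library` with subtype labels.
#' @export
rollup_to_subtype <- function(library) {
  if (anyNA(library$meta$subtype)) {
    stop("library rows lack subtype labels")
  }
  meta <- library$meta
  meta$label <- meta$subtype
  library_from_matrix(library$x, meta, library$grid)
}
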