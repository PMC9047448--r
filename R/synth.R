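#' Simulate a centroided single-pixel spectrum
#'
#' Draws one centroid per panel lipid at its exact m/z with intensity
#' `intensity_scale * abundance * noise`, where the noise is
#' multiplicative lognormal with unit mean and coefficient of variation
#' `noise_cv` (`noise_cv = 0` gives intensities exactly proportional to
#' the profile). A handful of sparse low-intensity background centroids
#' are added at off-panel masses, at least 0.05 Da away from every panel
#' species, to mimic matrix and chemical noise.
#'
#' @param profile A `cell_line_profile` from [make_profiles()].
#' @param panel The [lipid_panel] the profile is defined over.
#' @param intensity_scale Positive scale of the brightest possible signal.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer RNG seed.
#' @param n_background Number of background centroids (default 10).
#' @param coord,instrument Passed through to [centroid_spectrum()].
#' @return A [centroid_spectrum].
#' @export
synth_spectrum <- function(profile, panel = default_lipid_panel(),
                           intensity_scale = 1, noise_cv = 0.05, seed = 1,
                           n_background = 10L, coord = NULL,
                           instrument = NULL) {
  if (!is.numeric(intensity_scale) || intensity_scale <= 0) {
    stop("intensity_scale must be positive")
  }
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  ab <- profile$abundance
  if (length(ab) != nrow(panel)) stop("profile does not match panel size")
  with_seed(seed, {
    intens <- intensity_scale * ab
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      intens <- intens * stats::rlnorm(length(intens),
                                       meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    bg <- sample_background_mz(panel, n_background)
    bg_int <- intensity_scale * 2e-4 * stats::runif(length(bg))
    mz <- c(panel$mz, bg)
    it <- c(intens, bg_int)
    ord <- order(mz)
    centroid_spectrum(mz[ord], it[ord], coord = coord,
                      instrument = instrument)
  })
}

# Uniform draws over [600, 950) rejected within +/- 0.05 Da of any panel
# mass and de-duplicated so the centroid list stays strictly ascending.
sample_background_mz <- function(panel, n) {
  n <- as.integer(n)
  if (n <= 0) return(numeric(0))
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n && tries < 200L) {
    cand <- stats::runif(n, 600, 950)
    gap <- vapply(cand, function(m) min(abs(m - panel$mz)), numeric(1))
    out <- unique(c(out, cand[gap > 0.05]))
    tries <- tries + 1L
  }
  sort(out[seq_len(min(n, length(out)))])
}

# Background-only pixel: sparse matrix noise, no panel signal.
synth_background_spectrum <- function(panel, intensity_scale = 1,
                                      n_background = 10L, coord = NULL) {
  bg <- sample_background_mz(panel, n_background)
  centroid_spectrum(bg, intensity_scale * 2e-4 * stats::runif(length(bg)),
                    coord = coord)
}

#' Simulate a single-cell MSI acquisition
#'
#' Places non-overlapping disk-shaped cells on a pixel grid (a pixel
#' belongs to a cell when its center falls inside the disk) and fills
#' each cell's pixels with spectra drawn from its class profile via
#' [synth_spectrum()]. Remaining pixels carry background-only spectra.
#' Defaults emulate adherent cultured cells: 5 um pixels and cell
#' diameters uniform in 20-150 um, so every cell of diameter >= 20 um
#' covers at least 4 pixels.
#'
#' @param profiles List of `cell_line_profile` objects, one per class.
#' @param cells_per_class Number of cells to place for each class.
#' @param pixel_um Pixel size in micrometers (default 5).
#' @param diameter_range_um Length-2 numeric, cell diameter range in um.
#' @param noise_cv Per-centroid multiplicative noise CV.
#' @param seed Integer RNG seed.
#' @param panel The [lipid_panel] shared by all profiles.
#' @param dims Optional grid `(rows, cols)`; when `NULL` a square grid
#'   with roughly four times the total cell area is used.
#' @param intensity_scale Peak intensity scale handed to the spectrum
#'   simulator; cells get per-cell brightness jitter around this value.
#' @param max_place_tries Rejection-sampling attempts per cell before
#'   giving up with an error naming how many cells were placed.
#' @return List with elements `image` (a [spectrum_image]) and `truth`
#'   (a `ground_truth`: per-pixel `label` matrix and a list of disjoint
#'   `cell_masks`, each `(cell_id, pixels, label, subtype, diameter_um)`).
#' @export
synth_cell_image <- function(profiles, cells_per_class, pixel_um = 5,
                             diameter_range_um = c(20, 150),
                             noise_cv = 0.05, seed = 1,
                             panel = default_lipid_panel(), dims = NULL,
                             intensity_scale = 1, max_place_tries = 200L) {
  if (cells_per_class < 0) stop("cells_per_class must be >= 0")
  if (length(diameter_range_um) != 2 || diameter_range_um[1] <= 0 ||
      diameter_range_um[1] > diameter_range_um[2]) {
    stop("diameter_range_um must be a valid positive range")
  }
  n_cells <- length(profiles) * cells_per_class
  if (is.null(dims)) {
    mean_r <- mean(diameter_range_um) / 2
    area_um2 <- max(1, n_cells) * pi * mean_r^2 * 4
    side <- max(16L, as.integer(ceiling(sqrt(area_um2) / pixel_um)))
    dims <- c(side, side)
  }
  dims <- as.integer(dims)
  if (n_cells > 0 && diameter_range_um[2] > min(dims) * pixel_um) {
    stop("diameter range exceeds image extent")
  }
  with_seed(seed, {
    placed <- place_disks(n_cells, dims, pixel_um, diameter_range_um,
                          max_place_tries)
    if (nrow(placed) < n_cells) {
      stop(sprintf(
        "could only place %d of %d cells without overlap; enlarge dims or reduce cells",
        nrow(placed), n_cells))
    }
    label_mat <- matrix("BACKGROUND", dims[1], dims[2])
    spectra <- vector("list", dims[1] * dims[2])
    cell_masks <- vector("list", n_cells)
    k <- 0L
    for (i in seq_len(n_cells)) {
      prof <- profiles[[((i - 1L) %% length(profiles)) + 1L]]
      px <- disk_pixels(placed$cy[i], placed$cx[i], placed$r_um[i],
                        dims, pixel_um)
      cell_id <- sprintf("cell%03d", i)
      cell_scale <- intensity_scale * stats::runif(1, 0.7, 1.3)
      for (j in seq_len(nrow(px))) {
        k <- k + 1L
        spectra[[k]] <- synth_spectrum(
          prof, panel, intensity_scale = cell_scale, noise_cv = noise_cv,
          seed = sample.int(.Machine$integer.max, 1),
          coord = c(px$row[j], px$col[j]))
        label_mat[px$row[j] + 1L, px$col[j] + 1L] <- prof$label
      }
      cell_masks[[i]] <- list(cell_id = cell_id, pixels = px,
                              label = prof$label, subtype = prof$subtype,
                              diameter_um = 2 * placed$r_um[i])
    }
    # background pixels
    bg <- which(label_mat == "BACKGROUND", arr.ind = TRUE)
    for (j in seq_len(nrow(bg))) {
      k <- k + 1L
      spectra[[k]] <- synth_background_spectrum(
        panel, intensity_scale, coord = c(bg[j, 1] - 1L, bg[j, 2] - 1L))
    }
    image <- spectrum_image(spectra[seq_len(k)], dims, pixel_um,
                            metadata = list(kind = "synthetic-cells"))
    truth <- structure(list(label = label_mat, cell_masks = cell_masks),
                       class = "ground_truth")
    list(image = image, truth = truth)
  })
}

# Rejection-sample disk centers (um coordinates) so that disks stay inside
# the grid and pairwise gaps exceed one pixel.
place_disks <- function(n, dims, pixel_um, diameter_range_um, max_tries) {
  h <- dims[1] * pixel_um
  w <- dims[2] * pixel_um
  cy <- cx <- r_um <- numeric(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      r <- stats::runif(1, diameter_range_um[1] / 2, diameter_range_um[2] / 2)
      y <- stats::runif(1, r, h - r)
      x <- stats::runif(1, r, w - r)
      if (!length(cy) ||
          all(sqrt((cy - y)^2 + (cx - x)^2) > r + r_um + pixel_um)) {
        cy <- c(cy, y); cx <- c(cx, x); r_um <- c(r_um, r)
        ok <- TRUE
        break
      }
    }
    if (!ok) break
  }
  data.frame(cy = cy, cx = cx, r_um = r_um)
}

# Pixels whose centers fall inside the disk; 0-based (row, col).
disk_pixels <- function(cy, cx, r_um, dims, pixel_um) {
  r0 <- max(0L, floor((cy - r_um) / pixel_um) - 1L)
  r1 <- min(dims[1] - 1L, ceiling((cy + r_um) / pixel_um) + 1L)
  c0 <- max(0L, floor((cx - r_um) / pixel_um) - 1L)
  c1 <- min(dims[2] - 1L, ceiling((cx + r_um) / pixel_um) + 1L)
  g <- expand.grid(row = r0:r1, col = c0:c1)
  yc <- (g$row + 0.5) * pixel_um
  xc <- (g$col + 0.5) * pixel_um
  inside <- (yc - cy)^2 + (xc - cx)^2 <= r_um^2
  g[inside, , drop = FALSE]
}

#' Simulate a tissue MSI acquisition
#'
#' Builds a tissue image at histology resolution (default 30 um pixels):
#' a contiguous elliptical tumor region of `main_profile` spectra, a
#' contiguous necrotic subregion covering about `necrotic_fraction` of
#' the tumor pixels, and an unmeasured background border (real tissue
#' acquisitions only measure the sectioned area). Necrotic spectra are
#' the main profile mixed 50/50 with a uniform profile at 10% intensity:
#' dim and ratio-distorted, as necrosis presents to the classifier.
#'
#' @param main_profile `cell_line_profile` of the dominant tumor class.
#' @param necrotic_fraction Fraction of tumor pixels turned necrotic,
#'   in `[0, 1]`.
#' @param pixel_um Pixel size in micrometers (default 30).
#' @param dims Grid `(rows, cols)`, each >= 8.
#' @param noise_cv Per-centroid multiplicative noise CV.
#' @param seed Integer RNG seed.
#' @param panel The [lipid_panel].
#' @param intensity_scale Peak intensity scale for tumor pixels.
#' @param measure_background If `TRUE`, border pixels carry background
#'   spectra instead of being left unmeasured.
#' @return List with `image` (a [spectrum_image]) and `truth` (a
#'   `ground_truth` whose `label` matrix uses the main class label,
#'   `"NECROTIC"`, and `"BACKGROUND"`).
#' @export
synth_tissue_image <- function(main_profile, necrotic_fraction = 0.3,
                               pixel_um = 30, dims = c(64, 64),
                               noise_cv = 0.05, seed = 1,
                               panel = default_lipid_panel(),
                               intensity_scale = 1,
                               measure_background = FALSE) {
  if (necrotic_fraction < 0 || necrotic_fraction > 1) {
    stop("necrotic_fraction must lie in [0, 1]")
  }
  dims <- as.integer(dims)
  if (any(dims < 8)) stop("tissue images need dims >= (8, 8)")
  with_seed(seed, {
    rows <- dims[1]; cols <- dims[2]
    # elliptical tumor section centered in the grid
    cy <- (rows - 1) / 2; cx <- (cols - 1) / 2
    ry <- rows * 0.38; rx <- cols * 0.38
    g <- expand.grid(row = 0:(rows - 1), col = 0:(cols - 1))
    in_tumor <- ((g$row - cy) / ry)^2 + ((g$col - cx) / rx)^2 <= 1
    tumor <- g[in_tumor, , drop = FALSE]
    n_nec <- round(necrotic_fraction * nrow(tumor))
    nec_idx <- grow_region(tumor, n_nec)
    label_mat <- matrix("BACKGROUND", rows, cols)
    label_mat[cbind(tumor$row + 1L, tumor$col + 1L)] <- main_profile$label
    if (n_nec > 0) {
      label_mat[cbind(tumor$row[nec_idx] + 1L,
                      tumor$col[nec_idx] + 1L)] <- "NECROTIC"
    }
    necrotic_profile <- main_profile
    necrotic_profile$abundance <-
      0.5 * main_profile$abundance +
      0.5 * rep(1 / length(main_profile$abundance),
                length(main_profile$abundance))
    spectra <- vector("list", rows * cols)
    k <- 0L
    for (i in seq_len(nrow(tumor))) {
      k <- k + 1L
      nec <- n_nec > 0 && i %in% nec_idx
      spectra[[k]] <- synth_spectrum(
        if (nec) necrotic_profile else main_profile, panel,
        intensity_scale = intensity_scale * if (nec) 0.1 else 1,
        noise_cv = noise_cv, seed = sample.int(.Machine$integer.max, 1),
        coord = c(tumor$row[i], tumor$col[i]))
    }
    if (measure_background) {
      bg <- g[!in_tumor, , drop = FALSE]
      for (i in seq_len(nrow(bg))) {
        k <- k + 1L
        spectra[[k]] <- synth_background_spectrum(
          panel, intensity_scale, coord = c(bg$row[i], bg$col[i]))
      }
    }
    image <- spectrum_image(spectra[seq_len(k)], dims, pixel_um,
                            metadata = list(kind = "synthetic-tissue"))
    truth <- structure(list(label = label_mat, cell_masks = list()),
                       class = "ground_truth")
    list(image = image, truth = truth)
  })
}

# Contiguous subregion of `target` pixels: breadth-first growth over the
# 4-neighbour graph from a random interior pixel. Returns row indices
# into `pixels`.
grow_region <- function(pixels, target) {
  if (target <= 0) return(integer(0))
  target <- min(target, nrow(pixels))
  key <- paste(pixels$row, pixels$col)
  idx_of <- stats::setNames(seq_len(nrow(pixels)), key)
  start <- sample.int(nrow(pixels), 1)
  seen <- logical(nrow(pixels))
  seen[start] <- TRUE
  queue <- start
  out <- integer(0)
  while (length(queue) && length(out) < target) {
    cur <- queue[1]
    queue <- queue[-1]
    out <- c(out, cur)
    nb <- paste(pixels$row[cur] + c(-1L, 1L, 0L, 0L),
                pixels$col[cur] + c(0L, 0L, -1L, 1L))
    for (nk in nb) {
      j <- idx_of[nk]
      if (!is.na(j) && !seen[j]) {
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  out
}

#' Simulate a single-cell spectral library directly
#'
#' Shortcut past the imaging stage: draws `cells_per_class` single-cell
#' spectra per profile with [synth_spectrum()], rms-normalizes and bins
#' each onto `grid`, and assembles a `spectral_library`. Cells are
#' spread round-robin over `n_slides` slide ids, mimicking replicate
#' slides measured on different days.
#'
#' @param profiles List of `cell_line_profile` objects.
#' @param cells_per_class Spectra drawn per class.
#' @param noise_cv Per-centroid multiplicative noise CV.
#' @param seed Integer RNG seed.
#' @param grid Target [bin_grid].
#' @param panel The [lipid_panel] the profiles live on.
#' @param n_slides Number of slide ids to spread cells over (default 3).
#' @param ... Further arguments passed to [synth_spectrum()] (e.g.
#'   `n_background`).
#' @return A `spectral_library` with one row per simulated cell.
#' @export
synth_library <- function(profiles, cells_per_class, noise_cv = 0.05,
                          seed = 1, grid = bin_grid(),
                          panel = default_lipid_panel(), n_slides = 3L,
                          ...) {
  if (cells_per_class < 1) stop("cells_per_class must be >= 1")
  n <- length(profiles) * cells_per_class
  x <- matrix(0, nrow = n, ncol = grid$n_bins)
  meta <- data.frame(cell_id = character(n), label = character(n),
                     subtype = character(n), slide_id = character(n),
                     stringsAsFactors = FALSE)
  with_seed(seed, {
    r <- 0L
    for (prof in profiles) {
      for (j in seq_len(cells_per_class)) {
        r <- r + 1L
        s <- synth_spectrum(prof, panel, noise_cv = noise_cv,
                            seed = sample.int(.Machine$integer.max, 1), ...)
        x[r, ] <- bin_spectrum(rms_normalize(s), grid)$values
        meta$cell_id[r] <- sprintf("%s_c%03d", prof$label, j)
        meta$label[r] <- prof$label
        meta$subtype[r] <- prof$subtype
        meta$slide_id[r] <- sprintf("slide%d", ((j - 1L) %% n_slides) + 1L)
      }
    }
  })
  library_from_matrix(x, meta, grid)
}

#' Simulate per-instrument single-cell lipid profiles
#'
#' Draws `cells_per_instrument` single-cell spectra per instrument from
#' one class profile under the null of no instrument effect (identical
#' underlying ratios, independent multiplicative noise), and tabulates
#' the panel-lipid intensities in the long format that
#' [normalize_to_reference()] consumes.
#'
#' @param profile A `cell_line_profile`.
#' @param instruments Character vector of instrument ids.
#' @param cells_per_instrument Replicate cells per instrument.
#' @param noise_cv Per-centroid multiplicative noise CV.
#' @param seed Integer RNG seed.
#' @param panel The [lipid_panel].
#' @return Data frame with columns `instrument`, `cell_id`, `lipid`,
#'   `intensity`.
#' @export
synth_instrument_profiles <- function(profile, instruments,
                                      cells_per_instrument = 3,
                                      noise_cv = 0.05, seed = 1,
                                      panel = default_lipid_panel()) {
  if (cells_per_instrument < 1) stop("cells_per_instrument must be >= 1")
  rows <- list()
  with_seed(seed, {
    for (ins in instruments) {
      for (j in seq_len(cells_per_instrument)) {
        s <- synth_spectrum(profile, panel, noise_cv = noise_cv,
                            seed = sample.int(.Machine$integer.max, 1),
                            instrument = ins)
        idx <- match(panel$mz, s$mz)
        rows[[length(rows) + 1L]] <- data.frame(
          instrument = ins, cell_id = sprintf("%s_cell%d", ins, j),
          lipid = panel$name, intensity = s$intensity[idx],
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
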