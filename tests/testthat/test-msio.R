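make_small_image <- function(seed = 1) {
  s1 <- random_spectrum(15, seed);     s1$coord <- c(0L, 0L)
  s2 <- random_spectrum(12, seed + 1); s2$coord <- c(2L, 3L)
  spectrum_image(list(s1, s2), dims = c(4, 5), pixel_um = 5)
}

test_that("CSV spectrum tables round-trip at full float precision", {
  img <- make_small_image()
  path <- withr::local_tempfile(fileext = ".csv")
  write_image(img, path)
  back <- read_image(path, pixel_um = 5)
  for (co in list(c(0, 0), c(2, 3))) {
    a <- pixel_spectrum(img, co[1], co[2])
    b <- pixel_spectrum(back, co[1], co[2])
    expect_identical(a$mz, b$mz)
    expect_identical(a$intensity, b$intensity)
  }
})

test_that("a one-pixel two-centroid CSV reads into a one-pixel image", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("row,col,mz,intensity", "1,2,700.5,3", "1,2,800.25,4"), path)
  img <- read_image(path)
  expect_equal(n_pixels(img), 1L)
  s <- pixel_spectrum(img, 1, 2)
  expect_equal(s$mz, c(700.5, 800.25))
  expect_equal(s$intensity, c(3, 4))
})

test_that("malformed spectrum CSVs are reported with a line number", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("row,col,mz,intensity", "0,0,700.5,3", "0,0,,4"), path)
  expect_error(read_image(path), "line 3")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), path2)
  expect_error(read_image(path2), "need columns")
})

test_that("imzML round-trips bitwise, including the empty image", {
  img <- make_small_image(5)
  path <- file.path(withr::local_tempdir(), "img.imzML")
  write_image(img, path)
  back <- read_image(path)
  expect_identical(back$dims, img$dims)
  expect_equal(back$pixel_um, img$pixel_um)
  for (co in list(c(0, 0), c(2, 3))) {
    a <- pixel_spectrum(img, co[1], co[2])
    b <- pixel_spectrum(back, co[1], co[2])
    expect_identical(a$mz, b$mz)
    expect_identical(a$intensity, b$intensity)
  }
  empty <- spectrum_image(list(), dims = c(3, 3), pixel_um = 10)
  path2 <- file.path(withr::local_tempdir(), "empty.imzML")
  write_image(empty, path2)
  expect_equal(n_pixels(read_image(path2)), 0L)
})

test_that("imzML from the generator preserves the pixel count", {
  profs <- make_profiles(2, separation = 1, seed = 1)
  g <- synth_cell_image(profs, 2, noise_cv = 0.05, seed = 3,
                        diameter_range_um = c(20, 40), dims = c(40, 40))
  path <- file.path(withr::local_tempdir(), "cells.imzML")
  write_image(g$image, path)
  expect_equal(n_pixels(read_image(path)), n_pixels(g$image))
})

test_that("continuous-mode imzML is refused with centroiding advice", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cont.imzML")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    ' <fileDescription><fileContent>',
    '  <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous" value=""/>',
    ' </fileContent></fileDescription>',
    ' <run id="r"><spectrumList count="0"/></run>',
    '</mzML>'), path)
  writeBin(raw(16), file.path(dir, "cont.ibd"))
  expect_error(read_image(path), "centroid")
})

test_that("ROI tables read, group, and validate labels", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "roi.csv")
  writeLines(c("cell_id,row,col,label", "c1,0,0,A"), path)
  rois <- read_roi_table(path)
  expect_length(rois, 1)
  expect_equal(nrow(rois[[1]]$pixels), 1)
  expect_equal(rois[[1]]$label, "A")
  # conflicting labels within one cell
  writeLines(c("cell_id,row,col,label", "c1,0,0,A", "c1,0,1,B"), path)
  expect_error(read_roi_table(path), "conflicting")
  # shared pixel between cells: accepted with a warning
  writeLines(c("cell_id,row,col,label", "c1,0,0,A", "c2,0,0,B"), path)
  expect_warning(rois <- read_roi_table(path), "shared")
  expect_length(rois, 2)
})

test_that("ground-truth masks survive the ROI CSV round trip", {
  profs <- make_profiles(2, separation = 1, seed = 1)
  g <- synth_cell_image(profs, 2, noise_cv = 0, seed = 5,
                        diameter_range_um = c(20, 40), dims = c(40, 40))
  path <- file.path(withr::local_tempdir(), "roi.csv")
  write_roi_table(g$truth$cell_masks, path)
  rois <- read_roi_table(path)
  expect_length(rois, length(g$truth$cell_masks))
  for (i in seq_along(rois)) {
    m <- g$truth$cell_masks[[i]]
    r <- rois[[i]]
    expect_setequal(paste(r$pixels$row, r$pixels$col),
                    paste(m$pixels$row, m$pixels$col))
    expect_equal(r$label, m$label)
  }
})

test_that("label matrices round-trip through the label CSV dialect", {
  m <- matrix(c("A", "B", "A", "OUTLIER"), 2, 2)
  path <- file.path(withr::local_tempdir(), "lab.csv")
  write_label_csv(m, path)
  expect_identical(read_label_csv(path), m)
})

test_that("saved models classify identically to the in-memory model", {
  lib <- library3()
  m <- fit_model(lib, "CELL_LINE")
  path <- file.path(withr::local_tempdir(), "model.txt")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$projection, m$projection)
  expect_identical(m2$centroids, m$centroids)
  expect_identical(unname(m2$dispersions), unname(m$dispersions))
  # 100 held-out spectra classified identically, and on a held-out image
  fresh <- synth_library(make_profiles(3, separation = 1, seed = 3), 34,
                         noise_cv = 0.08, seed = 21)
  x <- fresh$x[1:100, ]
  expect_identical(msicelltyper:::classify_matrix(m, x, "outlier")$label,
                   msicelltyper:::classify_matrix(m2, x, "outlier")$label)
})

test_that("truncated or foreign model files are rejected", {
  lib <- library3()
  m <- fit_model(lib, "CELL_LINE")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.txt")
  write_model(m, path)
  lines <- readLines(path)
  trunc <- file.path(dir, "trunc.txt")
  writeLines(lines[1:(length(lines) - 5)], trunc)
  expect_error(read_model(trunc), "truncated")
  bad <- file.path(dir, "bad.txt")
  writeLines(c("msicelltyper-model/999", "end"), bad)
  expect_error(read_model(bad), "version|not a")
})

test_that("writers are atomic and leave no temp files behind", {
  dir <- withr::local_tempdir()
  img <- make_small_image()
  write_image(img, file.path(dir, "a.csv"))
  write_image(img, file.path(dir, "a.imzML"))
  expect_false(any(grepl("\\.tmp$", list.files(dir))))
})
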