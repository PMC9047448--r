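test_that("default lipid panel has 79 in-range species with the anchor PCs", {
  p <- default_lipid_panel()
  expect_s3_class(p, "lipid_panel")
  expect_equal(nrow(p), 79)
  expect_false(anyDuplicated(p$name) > 0)
  expect_true(all(p$mz >= 600 & p$mz < 950))
  expect_true(all(diff(p$mz) > 0))
  expect_equal(p$mz[p$name == "PC 34:1"], 760.585, tolerance = 1e-6)
  expect_equal(p$mz[p$name == "PC 36:1"], 788.61, tolerance = 1e-4)
})

test_that("profiles are normalized, subtype-labelled round-robin, and seeded", {
  profs <- make_profiles(14, separation = 1, seed = 1)
  expect_length(profs, 14)
  for (pr in profs) {
    expect_equal(sum(pr$abundance), 1, tolerance = 1e-9)
    expect_true(all(pr$abundance >= 0))
    expect_true(any(pr$abundance > 0))
  }
  expect_equal(vapply(profs[1:6], function(x) x$subtype, character(1)),
               rep(subtype_levels(), 2))
  # bitwise determinism
  expect_identical(profs, make_profiles(14, separation = 1, seed = 1))
  # distinct classes at positive separation
  ab <- vapply(profs, function(x) x$abundance, numeric(79))
  expect_gt(min(apply(ab, 2, stats::sd)), 0)
})

test_that("zero separation collapses all profiles onto the base profile", {
  profs <- make_profiles(5, separation = 0, seed = 9)
  for (i in 2:5) {
    expect_identical(unname(profs[[i]]$abundance), unname(profs[[1]]$abundance))
  }
})

test_that("make_profiles rejects an empty panel", {
  empty <- lipid_panel(character(0), numeric(0))
  expect_error(make_profiles(3, panel = empty), "empty")
})

test_that("synthetic spectra follow the profile exactly when noiseless", {
  panel <- default_lipid_panel()
  pr <- make_profiles(2, separation = 1, seed = 2)[[1]]
  s <- synth_spectrum(pr, panel, intensity_scale = 7, noise_cv = 0, seed = 5)
  idx <- match(panel$mz, s$mz)
  expect_false(anyNA(idx))
  expect_equal(s$intensity[idx], unname(7 * pr$abundance))
  # background centroids stay off-panel by more than 0.05 Da
  bg <- s$mz[-idx]
  expect_true(all(vapply(bg, function(m) min(abs(m - panel$mz)), numeric(1)) > 0.05))
  expect_error(synth_spectrum(pr, panel, intensity_scale = 0), "positive")
})

test_that("multiplicative noise reproduces the requested CV", {
  panel <- default_lipid_panel()
  pr <- make_profiles(1, separation = 0, seed = 1)[[1]]
  lip <- which(panel$name == "PC 34:1")
  draws <- vapply(seq_len(1000), function(i) {
    s <- synth_spectrum(pr, panel, noise_cv = 0.05, seed = 1000 + i)
    s$intensity[match(panel$mz[lip], s$mz)]
  }, numeric(1))
  cv_hat <- stats::sd(draws) / mean(draws)
  expect_lt(abs(cv_hat - 0.05) / 0.05, 0.2)
})

test_that("noiseless spectra of different classes bin to distinct vectors", {
  profs <- make_profiles(6, separation = 1, seed = 7)
  vecs <- lapply(profs, function(pr) {
    bin_spectrum(synth_spectrum(pr, noise_cv = 0, seed = 11), bin_grid())$values
  })
  for (i in 1:5) for (j in (i + 1):6) {
    expect_false(isTRUE(all.equal(vecs[[i]], vecs[[j]])))
  }
})

test_that("cell images place disjoint disk masks covering >= 4 pixels", {
  profs <- profiles14()
  g <- synth_cell_image(profs, 5, noise_cv = 0.05, seed = 7)
  masks <- g$truth$cell_masks
  expect_length(masks, 70)
  keys <- unlist(lapply(masks, function(m) paste(m$pixels$row, m$pixels$col)))
  expect_false(anyDuplicated(keys) > 0)  # pairwise disjoint
  for (m in masks) {
    expect_gte(nrow(m$pixels), 4)
    expect_true(all(g$truth$label[cbind(m$pixels$row + 1, m$pixels$col + 1)]
                    == m$label))
  }
  # every mask meets the geometric floor of its disk at this pixel size
  for (m in masks) {
    r_px <- m$diameter_um / 2 / g$image$pixel_um
    floor_px <- max(1, floor(pi * (r_px - sqrt(0.5))^2))
    expect_gte(nrow(m$pixels), floor_px)
  }
})

test_that("minimum-diameter cells still yield at least four spectra", {
  profs <- make_profiles(3, separation = 1, seed = 1)
  g <- synth_cell_image(profs, 3, diameter_range_um = c(20, 20),
                        noise_cv = 0, seed = 11)
  for (m in g$truth$cell_masks) expect_gte(nrow(m$pixels), 4)
})

test_that("a zero-cell image is background only", {
  profs <- make_profiles(2, separation = 1, seed = 1)
  g <- synth_cell_image(profs, 0, seed = 3, dims = c(16, 16))
  expect_length(g$truth$cell_masks, 0)
  expect_true(all(g$truth$label == "BACKGROUND"))
})

test_that("impossible placements fail with the count placed", {
  profs <- make_profiles(4, separation = 1, seed = 1)
  expect_error(
    synth_cell_image(profs, 10, dims = c(32, 32),
                     diameter_range_um = c(100, 150), seed = 1,
                     max_place_tries = 20),
    "could only place")
})

test_that("tissue images hit the requested necrotic share and are seeded", {
  pr <- profiles14()[[1]]
  tt <- synth_tissue_image(pr, necrotic_fraction = 0.3, dims = c(64, 64),
                           noise_cv = 0.05, seed = 4)
  lab <- tt$truth$label
  tumor_area <- sum(lab != "BACKGROUND")
  expect_lt(abs(sum(lab == "NECROTIC") / tumor_area - 0.3), 0.05)
  # zero fraction: every tumor pixel keeps the main class
  t0 <- synth_tissue_image(pr, necrotic_fraction = 0, dims = c(16, 16),
                           noise_cv = 0, seed = 5)
  expect_true(all(t0$truth$label %in% c(pr$label, "BACKGROUND")))
  # determinism
  t1 <- synth_tissue_image(pr, necrotic_fraction = 0.3, dims = c(24, 24),
                           noise_cv = 0.05, seed = 6)
  t2 <- synth_tissue_image(pr, necrotic_fraction = 0.3, dims = c(24, 24),
                           noise_cv = 0.05, seed = 6)
  expect_identical(t1$truth$label, t2$truth$label)
  expect_identical(t1$image$spectra[[10]], t2$image$spectra[[10]])
  expect_error(synth_tissue_image(pr, necrotic_fraction = 1.2), "0, 1")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(make_profiles(3, separation = 1, seed = 1))
  invisible(synth_spectrum(make_profiles(1, seed = 1)[[1]], seed = 2))
  expect_identical(.Random.seed, before)
})
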