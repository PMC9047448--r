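test_that("LDA projections and labels match the dense brute-force oracle", {
  for (seed in 1:3) {
    lib <- make_tiny_library(4, 3, seed)
    m <- fit_model(lib, "CELL_LINE", variance_kept = 1)
    oracle <- brute_force_lda(lib$x, lib$meta$label, d = 2)
    z_fit <- project_lda(m, lib$x)
    # per-direction sign is the only residual ambiguity
    for (j in 1:2) {
      s <- sign(sum(z_fit[, j] * oracle$z[, j]))
      expect_lt(max(abs(z_fit[, j] - s * oracle$z[, j])), 1e-8)
    }
    pred <- msicelltyper:::classify_matrix(m, lib$x, "force")$label
    oracle_pred <- vapply(seq_len(nrow(lib$x)), function(i) {
      d2 <- rowSums(sweep(oracle$centroids, 2, oracle$z[i, ])^2)
      oracle$classes[which.min(d2)]
    }, character(1))
    expect_identical(pred, oracle_pred)
  }
})

test_that("two noiseless classes separate along a single discriminant", {
  profs <- make_profiles(2, separation = 1, seed = 5)
  lib <- synth_library(profs, 3, noise_cv = 0, seed = 6)
  m <- fit_model(lib, "CELL_LINE")
  expect_equal(ncol(m$lda_basis), 1)
  pred <- msicelltyper:::classify_matrix(m, lib$x, "force")$label
  expect_identical(pred, lib$meta$label)
})

test_that("PCA keeps the smallest component count reaching the variance target", {
  lib <- library3()
  vk <- 0.9
  m <- fit_model(lib, "CELL_LINE", variance_kept = vk)
  # independent eigendecomposition of the library covariance
  ev <- eigen(stats::cov(lib$x), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-12]
  cum <- cumsum(ev) / sum(ev)
  k <- ncol(m$pca_basis)
  expect_gte(cum[k], vk)
  if (k > 1) expect_lt(cum[k - 1], vk)
  # PCA basis is orthonormal
  expect_equal(unname(crossprod(m$pca_basis)), diag(k), tolerance = 1e-8)
  expect_true(all(m$dispersions > 0))
})

test_that("the same library yields 14 cell-line or 3 subtype classes", {
  lib <- library14x16()
  m14 <- fit_model(lib, "CELL_LINE")
  m3 <- fit_model(lib, "SUBTYPE")
  expect_length(m14$classes, 14)
  expect_length(m3$classes, 3)
  expect_setequal(m3$classes, subtype_levels())
  expect_lte(ncol(m3$lda_basis), 2)
})

test_that("model fitting refuses degenerate class structure", {
  lib <- make_tiny_library(4, 3, 1)
  one_class <- msicelltyper:::subset_library(lib, lib$meta$label == "C1")
  expect_error(fit_model(one_class, "CELL_LINE"), "2 classes")
  uneven <- msicelltyper:::subset_library(lib, c(rep(TRUE, 5), rep(FALSE, 7)))
  expect_error(fit_model(uneven, "CELL_LINE"), "fewer than 2")
})

test_that("classification is exact at centroids and respects the modes", {
  profs <- make_profiles(3, separation = 1, seed = 5)
  lib <- synth_library(profs, 4, noise_cv = 0, seed = 6)
  m <- fit_model(lib, "CELL_LINE")
  # the class mean projects exactly onto its centroid: distance 0, never OUTLIER
  cl <- m$classes[1]
  preimage <- colMeans(lib$x[lib$meta$label == cl, , drop = FALSE])
  res <- classify(m, preimage, mode = "outlier")
  expect_equal(res$label, cl)
  expect_lt(res$distance[cl], 1e-8)
  # a vector displaced far beyond 3 dispersions is OUTLIER only in outlier mode
  set.seed(7)
  far <- lib$x[1, ] * runif(length(lib$x[1, ]), 0, 2) + 0.5
  expect_equal(classify(m, far, mode = "outlier")$label, "OUTLIER")
  expect_true(classify(m, far, mode = "force")$label %in% m$classes)
  # force mode never returns OUTLIER
  set.seed(8)
  for (i in 1:20) {
    v <- abs(rnorm(ncol(lib$x)))
    expect_true(classify(m, v, mode = "force")$label %in% m$classes)
  }
})

test_that("grid mismatches between vector and model are rejected", {
  lib <- make_tiny_library()
  m <- fit_model(lib, "CELL_LINE")
  fv <- bin_spectrum(centroid_spectrum(700.1, 1), bin_grid())
  expect_error(classify(m, fv), "grid")
})

test_that("stratified cross-validation is seeded, stratified, and recountable", {
  lib <- library14x16()
  cv <- crossval(lib, "CELL_LINE", k = 5, seed = 42)
  cv_again <- crossval(lib, "CELL_LINE", k = 5, seed = 42)
  expect_identical(cv$folds, cv_again$folds)
  expect_identical(cv$predictions, cv_again$predictions)
  # stratification: every class appears in every fold
  for (f in 1:5) {
    expect_setequal(unique(lib$meta$label[cv$folds == f]), lib$classes)
  }
  # recount oracle: rates recomputed from stored predictions
  pr <- cv$predictions
  n_out <- sum(pr$predicted == "OUTLIER")
  correct <- sum(pr$predicted == pr$truth)
  expect_equal(cv$rate_excluding_outliers,
               100 * correct / (nrow(pr) - n_out))
  expect_equal(cv$rate_including_outliers, 100 * correct / nrow(pr))
  expect_gte(cv$rate_excluding_outliers, cv$rate_including_outliers)
  # confusion matrix totals match
  expect_equal(sum(cv$confusion), nrow(pr))
})

test_that("noiseless well-separated libraries cross-validate at 100%", {
  profs <- make_profiles(14, separation = 1, seed = 9)
  lib <- synth_library(profs, 5, noise_cv = 0, seed = 10, n_background = 0)
  cv <- suppressWarnings(crossval(lib, "CELL_LINE", k = 5, seed = 1))
  expect_equal(cv$rate_excluding_outliers, 100)
  expect_equal(cv$rate_including_outliers, 100)
})

test_that("cross-validation refuses classes smaller than k", {
  profs <- make_profiles(3, separation = 1, seed = 2)
  lib <- synth_library(profs, 4, noise_cv = 0.05, seed = 3)
  expect_error(crossval(lib, "CELL_LINE", k = 5), "fewer than k")
})

test_that("holdout splits two-thirds / one-third per class", {
  profs <- make_profiles(3, separation = 1, seed = 4)
  lib <- synth_library(profs, 15, noise_cv = 0, seed = 5)
  rep <- holdout_validate(lib, "CELL_LINE", seed = 7)
  for (cl in lib$classes) {
    idx <- lib$meta$label == cl
    expect_equal(sum(rep$in_train[idx]), 10)  # round(2/3 * 15)
    expect_equal(sum(!rep$in_train[idx]), 5)
  }
  expect_equal(rep$rate_excluding_outliers, 100)
  # different seeds give different, equally sized splits
  rep2 <- holdout_validate(lib, "CELL_LINE", seed = 8)
  expect_false(identical(rep$in_train, rep2$in_train))
  expect_equal(sum(rep2$in_train), sum(rep$in_train))
  expect_error(holdout_validate(msicelltyper:::subset_library(
    lib, rep(c(TRUE, FALSE), length.out = nrow(lib$x))), "CELL_LINE"),
    NA)
})

test_that("spectra from an unseen class are rejected as outliers", {
  profs <- make_profiles(15, separation = 2, seed = 1)
  lib <- synth_library(profs[1:14], 16, noise_cv = 0.05, seed = 2)
  m <- fit_model(lib, "CELL_LINE")
  unseen <- synth_library(profs[15], 50, noise_cv = 0.05, seed = 3)
  pred <- msicelltyper:::classify_matrix(m, unseen$x, "outlier")$label
  expect_gte(mean(pred == "OUTLIER"), 0.9)
})
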