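#' Fit a PCA/LDA recognition model
#'
#' The deployable classifier: library rows are mean-centered, reduced by
#' PCA to the smallest number of components reaching `variance_kept`
#' cumulative explained variance, and a Fisher multiclass LDA with
#' pooled within-class covariance is fitted in PCA space. Discriminant
#' directions are scaled to unit pooled within-class variance, so
#' distances in discriminant space are in within-class standard
#' deviation units. Each class stores its centroid and a scalar
#' dispersion used by the outlier rule: a spectrum whose distance to the
#' winning centroid exceeds `outlier_multiplier` times that class's
#' dispersion is left unassigned.
#'
#' @param library A `spectral_library`.
#' @param label_level `"CELL_LINE"` (14-line model) or `"SUBTYPE"`
#'   (3-class receptor model; requires subtype metadata).
#' @param variance_kept Fraction of variance the PCA must retain
#'   (default 0.95).
#' @param outlier_multiplier Multiplier on the class dispersion
#'   (default 3).
#' @param dispersion_type How the scalar class dispersion is computed:
#'   `"rms_distance"` (default) is the root-mean-square distance of the
#'   class's training points to their centroid, so the rule bounds the
#'   full discriminant-space distance; `"per_direction"` is the root of
#'   the mean per-direction variance about the centroid.
#' @param seed Unused (fitting is deterministic); accepted so callers
#'   can treat all pipeline stages uniformly.
#' @return An object of class `recognition_model`.
#' @export
fit_model <- function(library, label_level = c("CELL_LINE", "SUBTYPE"),
                      variance_kept = 0.95, outlier_multiplier = 3,
                      dispersion_type = c("rms_distance", "per_direction"),
                      seed = NULL) {
  label_level <- match.arg(label_level)
  dispersion_type <- match.arg(dispersion_type)
  if (outlier_multiplier <= 0) stop("outlier_multiplier must be positive")
  if (variance_kept <= 0 || variance_kept > 1) {
    stop("variance_kept must be in (0, 1]")
  }
  labels <- model_labels(library, label_level)
  tab <- table(labels)
  if (length(tab) < 2) stop("model fitting needs at least 2 classes")
  if (any(tab < 2)) {
    stop(sprintf("class(es) with fewer than 2 cells: %s",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  x <- library$x
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  pc <- stats::prcomp(xc, center = FALSE)
  sdev <- pc$sdev
  keep_nz <- sdev > sdev[1] * 1e-12
  var_share <- sdev[keep_nz]^2 / sum(sdev[keep_nz]^2)
  k <- which(cumsum(var_share) >= variance_kept - 1e-12)[1]
  if (is.na(k)) k <- sum(keep_nz)
  rotation <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- xc %*% rotation
  classes <- sort(unique(labels))
  C <- length(classes)
  class_means <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(scores[labels == cl, , drop = FALSE])
  }))
  grand <- colMeans(scores)
  # pooled within-class covariance and between-class scatter in PCA space
  sw <- matrix(0, k, k)
  sb <- matrix(0, k, k)
  for (ci in seq_len(C)) {
    sc <- scores[labels == classes[ci], , drop = FALSE]
    dev <- sweep(sc, 2, class_means[ci, ])
    sw <- sw + crossprod(dev)
    db <- class_means[ci, ] - grand
    sb <- sb + nrow(sc) * tcrossprod(db)
  }
  sw <- sw / (n - C)
  ew <- eigen(sw, symmetric = TRUE)
  if (min(ew$values) <= max(ew$values) * 1e-10) {
    warning("pooled within-class covariance near-singular; adding ridge")
    # floor relative to the between-class scale so whitening stays finite
    # even when the within-class scatter is exactly zero
    ridge <- max(max(ew$values) * 1e-8, mean(diag(sb)) * 1e-10, 1e-12)
    sw <- sw + diag(ridge, k)
    ew <- eigen(sw, symmetric = TRUE)
  }
  whiten <- ew$vectors %*% diag(1 / sqrt(ew$values), k)
  m2 <- crossprod(whiten, sb) %*% whiten
  m2 <- (m2 + t(m2)) / 2
  eb <- eigen(m2, symmetric = TRUE)
  d <- min(C - 1L, k)
  lda_basis <- whiten %*% eb$vectors[, seq_len(d), drop = FALSE]
  # canonical sign: largest-magnitude loading positive
  for (j in seq_len(d)) {
    v <- lda_basis[, j]
    if (v[which.max(abs(v))] < 0) lda_basis[, j] <- -v
  }
  z <- scores %*% lda_basis
  centroids <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(z[labels == cl, , drop = FALSE])
  }))
  dispersions <- vapply(seq_len(C), function(ci) {
    zc <- z[labels == classes[ci], , drop = FALSE]
    dev <- sweep(zc, 2, centroids[ci, ])
    disp <- if (dispersion_type == "rms_distance") {
      sqrt(sum(dev^2) / max(1, nrow(zc) - 1))
    } else {
      sqrt(mean(apply(dev, 2, stats::var)))
    }
    if (disp == 0) disp <- 1e-8 * (1 + sqrt(sum(centroids[ci, ]^2)))
    disp
  }, numeric(1))
  rownames(centroids) <- classes
  names(dispersions) <- classes
  structure(list(
    version = "msicelltyper-model/1",
    grid = library$grid,
    label_level = label_level,
    classes = classes,
    mean = mu,
    pca_basis = rotation,
    explained = var_share[seq_len(k)],
    lda_basis = lda_basis,
    projection = rotation %*% lda_basis,
    centroids = centroids,
    dispersions = dispersions,
    outlier_multiplier = outlier_multiplier,
    dispersion_type = dispersion_type,
    lda_eigenvalues = eb$values[seq_len(d)],
    n_train = n
  ), class = "recognition_model")
}

model_labels <- function(library, label_level) {
  if (label_level == "CELL_LINE") {
    library$meta$label
  } else {
    if (anyNA(library$meta$subtype)) {
      stop("subtype-level model needs subtype metadata on every row")
    }
    library$meta$subtype
  }
}

#' @export
print.recognition_model <- function(x, ...) {
  cat(sprintf(
    "<recognition_model (%s): %d classes, %d PCA components (%.1f%% var), %d LDA directions, outlier SD x %g>\n",
    x$label_level, length(x$classes), ncol(x$pca_basis),
    100 * sum(x$explained), ncol(x$lda_basis), x$outlier_multiplier))
  invisible(x)
}

#' Project binned spectra into discriminant space
#'
#' @param model A `recognition_model`.
#' @param x Numeric matrix (spectra x bins) on the model's grid.
#' @return Matrix of discriminant coordinates (spectra x directions).
#' @export
project_lda <- function(model, x) {
  if (ncol(x) != length(model$mean)) {
    stop("feature length does not match the model grid")
  }
  sweep(x, 2, model$mean) %*% model$projection
}

#' Classify a binned spectrum
#'
#' Projects the spectrum into discriminant space and assigns the class
#' with the nearest centroid (Euclidean distance; ties broken by
#' lexicographic class label). In `outlier` mode, a spectrum whose
#' winning distance exceeds `outlier_multiplier` times the winning
#' class's dispersion is returned as `"OUTLIER"`; `force` mode always
#' returns the nearest class.
#'
#' @param model A `recognition_model`.
#' @param vector A `feature_vector` on the model's grid, or a plain
#'   numeric vector of bin values.
#' @param mode `"outlier"` (default) or `"force"`.
#' @return List with `label` and `distance` (named vector of distances
#'   to every class centroid).
#' @export
classify <- function(model, vector, mode = c("outlier", "force")) {
  mode <- match.arg(mode)
  if (inherits(vector, "feature_vector")) {
    if (!grids_equal(vector$grid, model$grid)) {
      stop("feature grid does not match the model grid")
    }
    vector <- vector$values
  }
  res <- classify_matrix(model, matrix(vector, nrow = 1), mode)
  list(label = res$label[1], distance = res$distance[1, ])
}

# Vectorized nearest-centroid classification of a spectra x bins matrix.
classify_matrix <- function(model, x, mode = c("outlier", "force")) {
  mode <- match.arg(mode)
  z <- project_lda(model, x)
  cent <- model$centroids
  # squared distances via ||z||^2 - 2 z c' + ||c||^2
  d2 <- outer(rowSums(z^2), rep(1, nrow(cent))) -
    2 * z %*% t(cent) +
    outer(rep(1, nrow(z)), rowSums(cent^2))
  d2[d2 < 0] <- 0
  dist <- sqrt(d2)
  colnames(dist) <- model$classes
  win <- apply(dist, 1, which.min)  # first minimum = lexicographic tie-break
  label <- model$classes[win]
  if (mode == "outlier") {
    wd <- dist[cbind(seq_along(win), win)]
    thr <- model$outlier_multiplier * model$dispersions[win]
    label[wd > thr] <- "OUTLIER"
  }
  list(label = label, distance = dist)
}

#' Stratified k-fold cross-validation
#'
#' Evaluates the recognition model the way its classification rates are
#' reported: rows are split into `k` stratified folds (each fold holds a
#' representative share of every class), a model is fitted on the other
#' folds and the held-out fold is classified in outlier mode. Two rates
#' are reported: excluding outliers (correct / non-outlier predictions)
#' and including outliers (correct / all, outliers counted as wrong).
#'
#' @param library A `spectral_library`.
#' @param label_level `"CELL_LINE"` or `"SUBTYPE"`.
#' @param k Number of folds (default 5); every class needs >= k rows.
#' @param outlier_multiplier Outlier rule multiplier (default 3).
#' @param variance_kept Passed to [fit_model()].
#' @param dispersion_type Passed to [fit_model()].
#' @param seed Integer seed fixing the fold assignment.
#' @return A `cv_report`: `folds` (per-row fold index), `predictions`
#'   (data frame of truth/prediction per row), `confusion`,
#'   `rate_excluding_outliers`, `rate_including_outliers` (percent).
#' @export
crossval <- function(library, label_level = c("CELL_LINE", "SUBTYPE"),
                     k = 5, outlier_multiplier = 3, variance_kept = 0.95,
                     dispersion_type = c("rms_distance", "per_direction"),
                     seed = 1) {
  label_level <- match.arg(label_level)
  dispersion_type <- match.arg(dispersion_type)
  labels <- model_labels(library, label_level)
  tab <- table(labels)
  if (any(tab < k)) {
    stop(sprintf("class(es) with fewer than k=%d rows: %s", k,
                 paste(names(tab)[tab < k], collapse = ", ")))
  }
  n <- nrow(library$x)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  pred <- character(n)
  for (f in seq_len(k)) {
    test <- folds == f
    train_lib <- subset_library(library, !test)
    m <- fit_model(train_lib, label_level, variance_kept = variance_kept,
                   outlier_multiplier = outlier_multiplier,
                   dispersion_type = dispersion_type)
    pred[test] <- classify_matrix(
      m, library$x[test, , drop = FALSE], mode = "outlier")$label
  }
  cv_report(labels, pred, folds)
}

subset_library <- function(library, keep) {
  library_from_matrix(library$x[keep, , drop = FALSE],
                      library$meta[keep, , drop = FALSE], library$grid)
}

cv_report <- function(truth, pred, folds) {
  correct <- sum(pred == truth)
  n <- length(truth)
  n_out <- sum(pred == "OUTLIER")
  structure(list(
    folds = folds,
    predictions = data.frame(truth = truth, predicted = pred,
                             fold = folds, stringsAsFactors = FALSE),
    confusion = table(truth = truth, predicted = pred),
    n = n,
    n_outliers = n_out,
    rate_excluding_outliers =
      if (n > n_out) 100 * correct / (n - n_out) else NA_real_,
    rate_including_outliers = 100 * correct / n
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report: n=%d, %.2f%% excluding outliers, %.2f%% including (%d outliers)>\n",
    x$n, x$rate_excluding_outliers, x$rate_including_outliers,
    x$n_outliers))
  invisible(x)
}

#' Holdout validation at a fixed training fraction
#'
#' Per-class stratified split: `round(train_fraction * class size)`
#' cells (at least 2) train the model, the rest are classified in
#' outlier mode. With the default 2/3 fraction this reproduces the
#' two-thirds / one-third training/validation design.
#'
#' @inheritParams crossval
#' @param train_fraction Fraction of each class used for training
#'   (default 2/3); every class needs >= 3 rows.
#' @return A `cv_report` (folds: 0 = train, 1 = validation; rates over
#'   the validation rows only).
#' @export
holdout_validate <- function(library,
                             label_level = c("CELL_LINE", "SUBTYPE"),
                             train_fraction = 2 / 3,
                             outlier_multiplier = 3, variance_kept = 0.95,
                             dispersion_type = c("rms_distance",
                                                 "per_direction"),
                             seed = 1) {
  label_level <- match.arg(label_level)
  dispersion_type <- match.arg(dispersion_type)
  labels <- model_labels(library, label_level)
  tab <- table(labels)
  if (any(tab < 3)) {
    stop(sprintf("class(es) with fewer than 3 rows: %s",
                 paste(names(tab)[tab < 3], collapse = ", ")))
  }
  n <- nrow(library$x)
  in_train <- logical(n)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      n_tr <- max(2L, as.integer(round(train_fraction * length(idx))))
      n_tr <- min(n_tr, length(idx) - 1L)
      in_train[sample(idx, n_tr)] <- TRUE
    }
  })
  m <- fit_model(subset_library(library, in_train), label_level,
                 variance_kept = variance_kept,
                 outlier_multiplier = outlier_multiplier,
                 dispersion_type = dispersion_type)
  pred <- classify_matrix(m, library$x[!in_train, , drop = FALSE],
                          mode = "outlier")$label
  rep <- cv_report(labels[!in_train], pred, folds = rep(1L, sum(!in_train)))
  rep$in_train <- in_train
  rep$model <- m
  rep
}
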