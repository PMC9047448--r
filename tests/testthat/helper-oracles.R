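# Independent dense Fisher LDA: scatter matrices accumulated by explicit
# loops in original bin space, generalized eigenproblem solved via
# solve(Sw) %*% Sb, directions rescaled to unit pooled within-class
# variance. Deliberately a different route than the fitted model's
# PCA-space symmetric whitening.
brute_force_lda <- function(x, labels, d) {
  mu <- colMeans(x)
  classes <- sort(unique(labels))
  p <- ncol(x)
  sw <- matrix(0, p, p)
  sb <- matrix(0, p, p)
  for (cl in classes) {
    xc <- x[labels == cl, , drop = FALSE]
    m <- colMeans(xc)
    for (i in seq_len(nrow(xc))) {
      dv <- xc[i, ] - m
      sw <- sw + outer(dv, dv)
    }
    db <- m - mu
    sb <- sb + nrow(xc) * outer(db, db)
  }
  sw <- sw / (nrow(x) - length(classes))
  e <- eigen(solve(sw) %*% sb)
  keep <- order(Re(e$values), decreasing = TRUE)[seq_len(d)]
  basis <- Re(e$vectors[, keep, drop = FALSE])
  for (j in seq_len(d)) {
    v <- basis[, j]
    v <- v / sqrt(drop(t(v) %*% sw %*% v))  # unit within-class variance
    if (v[which.max(abs(v))] < 0) v <- -v
    basis[, j] <- v
  }
  z <- sweep(x, 2, mu) %*% basis
  cent <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(z[labels == cl, , drop = FALSE])
  }))
  rownames(cent) <- classes
  list(z = z, centroids = cent, classes = classes)
}

make_tiny_library <- function(n_per = 4, n_classes = 3, seed = 1) {
  set.seed(seed)
  n <- n_per * n_classes
  centers <- matrix(runif(n_classes * 5, 1, 4), n_classes, 5)
  x <- do.call(rbind, lapply(seq_len(n_classes), function(ci) {
    sweep(matrix(rnorm(n_per * 5, sd = 0.3), n_per, 5), 2,
          centers[ci, ], `+`)
  }))
  x <- abs(x)
  labels <- rep(sprintf("C%d", seq_len(n_classes)), each = n_per)
  library_from_matrix(
    x, data.frame(cell_id = sprintf("c%02d", 1:n), label = labels,
                  subtype = rep(subtype_levels(), length.out = n)),
    tiny_grid())
}

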