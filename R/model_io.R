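# Portable text serialization for recognition models.
#
# Versioned key/value format, one field per record:
#   msicelltyper-model/1
#   scalar <name> <value>
#   string <name> <value>
#   strings <name> <n> / one line of tab-separated values
#   vector <name> <n> / one line of space-separated %.17g numbers
#   matrix <name> <nrow> <ncol> / nrow lines of space-separated numbers
#   end
# %.17g preserves doubles bitwise across write/read.

fmt_nums <- function(x) paste(sprintf("%.17g", x), collapse = " ")

#' Save a recognition model to a portable text file
#'
#' All numeric members survive the round trip bitwise; the format is
#' versioned and plain text so models can move between implementations.
#'
#' @param model A `recognition_model` from [fit_model()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "recognition_model"))
  lines <- c(
    "msicelltyper-model/1",
    sprintf("string label_level %s", model$label_level),
    sprintf("string dispersion_type %s", model$dispersion_type),
    sprintf("scalar outlier_multiplier %s", sprintf("%.17g", model$outlier_multiplier)),
    sprintf("scalar n_train %d", model$n_train),
    sprintf("scalar grid_lo %s", sprintf("%.17g", model$grid$lo)),
    sprintf("scalar grid_hi %s", sprintf("%.17g", model$grid$hi)),
    sprintf("scalar grid_width %s", sprintf("%.17g", model$grid$width)),
    sprintf("strings classes %d", length(model$classes)),
    paste(model$classes, collapse = "\t"),
    sprintf("vector mean %d", length(model$mean)),
    fmt_nums(model$mean),
    sprintf("vector explained %d", length(model$explained)),
    fmt_nums(model$explained),
    sprintf("vector dispersions %d", length(model$dispersions)),
    fmt_nums(model$dispersions),
    sprintf("vector lda_eigenvalues %d", length(model$lda_eigenvalues)),
    fmt_nums(model$lda_eigenvalues),
    mat_lines("pca_basis", model$pca_basis),
    mat_lines("lda_basis", model$lda_basis),
    mat_lines("centroids", model$centroids),
    "end"
  )
  atomic_write(path, function(tmp) writeLines(lines, tmp))
}

mat_lines <- function(name, m) {
  c(sprintf("matrix %s %d %d", name, nrow(m), ncol(m)),
    vapply(seq_len(nrow(m)), function(i) fmt_nums(m[i, ]), character(1)))
}

#' Load a recognition model saved by [write_model()]
#'
#' @param path Path to the model file.
#' @return A `recognition_model`.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "msicelltyper-model/1") {
    stop(sprintf("%s is not a msicelltyper-model/1 file (version mismatch?)",
                 path))
  }
  if (lines[length(lines)] != "end") {
    stop(sprintf("model file %s is truncated", path))
  }
  fields <- list()
  i <- 2L
  while (i <= length(lines) && lines[i] != "end") {
    parts <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    kind <- parts[1]
    name <- parts[2]
    if (kind == "scalar") {
      fields[[name]] <- as.numeric(parts[3])
      i <- i + 1L
    } else if (kind == "string") {
      fields[[name]] <- paste(parts[-(1:2)], collapse = " ")
      i <- i + 1L
    } else if (kind == "strings") {
      fields[[name]] <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
      i <- i + 2L
    } else if (kind == "vector") {
      v <- as.numeric(strsplit(lines[i + 1L], " ", fixed = TRUE)[[1]])
      if (length(v) != as.integer(parts[3])) {
        stop(sprintf("model file %s: field %s truncated", path, name))
      }
      fields[[name]] <- v
      i <- i + 2L
    } else if (kind == "matrix") {
      nr <- as.integer(parts[3]); nc <- as.integer(parts[4])
      if (i + nr > length(lines)) {
        stop(sprintf("model file %s: field %s truncated", path, name))
      }
      rows <- lapply(lines[(i + 1L):(i + nr)], function(ln) {
        as.numeric(strsplit(ln, " ", fixed = TRUE)[[1]])
      })
      if (any(vapply(rows, length, integer(1)) != nc)) {
        stop(sprintf("model file %s: field %s truncated", path, name))
      }
      fields[[name]] <- do.call(rbind, rows)
      i <- i + nr + 1L
    } else {
      stop(sprintf("model file %s: unknown record '%s'", path, kind))
    }
  }
  need <- c("label_level", "dispersion_type", "outlier_multiplier",
            "grid_lo", "grid_hi", "grid_width", "classes", "mean",
            "explained", "dispersions", "lda_eigenvalues", "pca_basis",
            "lda_basis", "centroids")
  missing <- setdiff(need, names(fields))
  if (length(missing)) {
    stop(sprintf("model file %s is missing field(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  centroids <- fields$centroids
  rownames(centroids) <- fields$classes
  dispersions <- fields$dispersions
  names(dispersions) <- fields$classes
  structure(list(
    version = "msicelltyper-model/1",
    grid = bin_grid(fields$grid_lo, fields$grid_hi, fields$grid_width),
    label_level = fields$label_level,
    classes = fields$classes,
    mean = fields$mean,
    pca_basis = fields$pca_basis,
    explained = fields$explained,
    lda_basis = fields$lda_basis,
    projection = fields$pca_basis %*% fields$lda_basis,
    centroids = centroids,
    dispersions = dispersions,
    outlier_multiplier = fields$outlier_multiplier,
    dispersion_type = fields$dispersion_type,
    lda_eigenvalues = fields$lda_eigenvalues,
    n_train = as.integer(fields$n_train %||% NA_integer_)
  ), class = "recognition_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
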