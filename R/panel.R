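#' Lipid panel
#'
#' An ordered panel of singly protonated lipid species: the set of m/z
#' channels the synthetic generator places signal at and that the
#' classification pipeline resolves. Masses must lie strictly inside the
#' model mass range [600, 950) Da.
#'
#' @param name Character vector of unique lipid names.
#' @param mz Numeric vector of `[M+H]+` centroid masses (Da), same length,
#'   strictly ascending after sorting.
#' @return A data frame of class `lipid_panel` with columns `name`, `mz`,
#'   sorted ascending by `mz`.
#' @export
lipid_panel <- function(name, mz) {
  name <- as.character(name)
  mz <- as.numeric(mz)
  if (length(name) != length(mz)) stop("name and mz must have equal length")
  if (anyDuplicated(name)) stop("lipid names must be unique")
  if (any(mz < 600 | mz >= 950)) {
    stop("all panel masses must lie inside [600, 950) Da")
  }
  ord <- order(mz)
  name <- name[ord]
  mz <- mz[ord]
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    stop("panel masses must be strictly ascending (no duplicates)")
  }
  structure(data.frame(name = name, mz = mz, stringsAsFactors = FALSE),
            class = c("lipid_panel", "data.frame"))
}

#' Default 79-lipid panel
#'
#' A fixed panel of 79 phospholipid-like species spanning m/z 600-950,
#' built from homologous series (DG, PE, SM, PG, PC, TG) on the usual
#' 14.01565 Da (CH2) and 2.01565 Da (H2, one double bond) spacings.
#' The anchors PC 34:1 (m/z 760.585) and PC 36:1 (m/z 788.616) are
#' members; other masses are plausible but arbitrary and fixed in code.
#'
#' @return A [lipid_panel] with 79 entries.
#' @export
default_lipid_panel <- function() {
  ch2 <- 14.01565
  h2 <- 2.01565
  series <- function(fam, base, base_c, carbons, dbs) {
    g <- expand.grid(n = carbons, k = dbs)
    data.frame(
      name = sprintf("%s %d:%d", fam, g$n, g$k),
      mz = base + (g$n - base_c) * ch2 - g$k * h2,
      stringsAsFactors = FALSE
    )
  }
  entries <- rbind(
    series("DG", 605.5503, 36, seq(36, 40, 2), 0:1),
    series("PE", 720.5538, 34, seq(32, 40, 2), 0:2),
    series("SM", 705.5905, 34, seq(34, 42, 2), 1:2),
    series("PG", 751.5484, 34, seq(32, 38, 2), 0:2),
    series("PC", 762.6007, 34, seq(30, 44, 2), 0:3),
    series("TG", 850.7858, 50, seq(50, 56, 2), 1)
  )
  lipid_panel(entries$name, entries$mz)
}

#' @export
print.lipid_panel <- function(x, ...) {
  cat(sprintf("<lipid_panel: %d species, m/z %.3f-%.3f>\n",
              nrow(x), min(x$mz), max(x$mz)))
  invisible(x)
}

#' Receptor subtype labels
#'
#' The three breast-cancer receptor subtypes the pipeline distinguishes:
#' triple negative (ER-/PR-/HER2-), HER2 positive, and ER+/PR+ positive.
#'
#' @return Character vector of the three subtype labels.
#' @export
subtype_levels <- function() c("TRIPLE_NEG", "HER2_POS", "ER_PR_POS")

# Run code under a private RNG state: set.seed(seed), restore afterwards so
# generators are pure functions of their arguments and never perturb the
# caller's stream.
with_seed <- function(seed, code) {
  force(seed)  # draw caller-supplied seeds before snapshotting the state
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Ground-truth cell-line lipid profiles
#'
#' Draws `n_classes` relative-abundance profiles over a lipid panel.
#' All classes share one Dirichlet-drawn base profile; each class is a
#' log-scale perturbation of that base, so classes differ in the ratios
#' of the same lipids rather than in lipid presence. The perturbation
#' has two sparse components: one shared by all cell lines of the same
#' receptor subtype (subtypes are assigned round-robin over
#' [subtype_levels()]) and one specific to the cell line, both scaled by
#' `separation`. `separation = 0` returns identical copies of the base
#' profile; larger values spread the classes further apart.
#'
#' @param n_classes Number of cell-line classes (>= 1).
#' @param panel A [lipid_panel]; defaults to [default_lipid_panel()].
#' @param separation Non-negative scale of the class perturbations.
#' @param seed Integer RNG seed; output is a pure function of arguments.
#' @return List of `cell_line_profile` objects, each with fields `label`,
#'   `subtype`, and `abundance` (named non-negative vector summing to 1).
#' @export
make_profiles <- function(n_classes, panel = default_lipid_panel(),
                          separation = 1, seed = 1) {
  if (!inherits(panel, "lipid_panel")) stop("panel must be a lipid_panel")
  if (nrow(panel) == 0) stop("cannot draw profiles over an empty panel")
  if (n_classes < 1) stop("n_classes must be >= 1")
  if (separation < 0) stop("separation must be non-negative")
  p <- nrow(panel)
  subs <- subtype_levels()
  n_sub_support <- max(4L, min(p, ceiling(p * 0.10)))
  n_cls_support <- max(4L, min(p, ceiling(p * 0.15)))
  with_seed(seed, {
    base <- stats::rgamma(p, shape = 2)
    base <- base / sum(base)
    subtype_delta <- lapply(subs, function(s) {
      d <- numeric(p)
      idx <- sample.int(p, n_sub_support)
      d[idx] <- stats::rnorm(n_sub_support)
      d
    })
    names(subtype_delta) <- subs
    lapply(seq_len(n_classes), function(i) {
      subtype <- subs[((i - 1L) %% 3L) + 1L]
      d <- numeric(p)
      idx <- sample.int(p, n_cls_support)
      d[idx] <- stats::rnorm(n_cls_support)
      ab <- base * exp(separation * (subtype_delta[[subtype]] + d))
      ab <- ab / sum(ab)
      names(ab) <- panel$name
      structure(
        list(label = sprintf("LINE%02d", i), subtype = subtype,
             abundance = ab),
        class = "cell_line_profile"
      )
    })
  })
}

#' @export
print.cell_line_profile <- function(x, ...) {
  cat(sprintf("<cell_line_profile %s (%s): %d lipids, top %s>\n",
              x$label, x$subtype, length(x$abundance),
              names(x$abundance)[which.max(x$abundance)]))
  invisible(x)
}
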